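## cli_pipeline: orchestrators that run each analysis end-to-end from a
## single config list, with fixed seeds, self-describing TSV outputs and a
## JSON MANIFEST of completed stages. All hand-off between stages is via
## files or returned objects -- no hidden state -- so any stage can be
## re-run independently. The numbered scripts under analysis/ are thin
## drivers over these functions.

write_manifest <- function(out_dir, stages, config_echo, error = NULL) {
  manifest <- list(
    tool = "coevkit",
    version = as.character(utils::packageVersion("coevkit")),
    completed_stages = stages,
    config = config_echo,
    error = if (is.null(error)) NULL else conditionMessage(error)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "MANIFEST.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = NA)
}

config_echo <- function(config) {
  if (is.null(config) || is.atomic(config)) return(config)
  if (is.data.frame(config)) return(paste(class(config), collapse = "/"))
  if (is.list(config)) return(lapply(unclass(config), config_echo))
  paste(class(config), collapse = "/")
}

run_with_manifest <- function(out_dir, config, body) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- character(0)
  note <- function(stage) stages[[length(stages) + 1L]] <<- stage
  result <- tryCatch(body(note), error = function(e) {
    write_manifest(out_dir, stages, config_echo(config), error = e)
    stop(e)
  })
  write_manifest(out_dir, stages, config_echo(config))
  result
}

#' Run the ortholog-curation + conservation + coevolution pipeline
#'
#' In simulation mode (`config$sim` is an [msa_sim_config()]) the full chain
#' runs: generate families -> deduplicate strains -> one-to-one assignment
#' against the paralog decoy -> partner partition -> per-set conservation
#' profiles -> region comparison, and the result is scored against the
#' planted truth. In pre-aligned mode (`config$aln_pos` / `config$aln_neg`
#' are FASTA paths) curation is skipped and the comparison runs on the
#' supplied alignments.
#'
#' @param config list with elements: `sim` or (`aln_pos`, `aln_neg`,
#'   `reference_id`); `region` (reference-residue interval; defaults to the
#'   simulated region or the C-terminal interface preset); `params`
#'   ([cons_params()]); `n_perm`; `seed`; `out_dir`.
#' @return list: `comparison` (a `region_comparison`), plus in simulation
#'   mode `assignment`, `partition`, `truth_recovery` (fraction of planted
#'   organisms assigned their planted ortholog, and whether the paralog was
#'   ever assigned).
#' @export
run_coevolution <- function(config) {
  out_dir <- config$out_dir %||% tempfile("coevo_run_")
  params <- config$params %||% cons_params()
  n_perm <- config$n_perm %||% 999L
  seed <- config$seed %||% abort("config$seed is required")

  run_with_manifest(out_dir, config, function(note) {
    if (!is.null(config$sim)) {
      fam <- simulate_ortholog_families(config$sim)
      note("simulate")
      region <- config$region %||% config$sim$region

      candidates <- rbind(fam$partner_pos, fam$partner_neg)
      dedup <- deduplicate_strains(candidates, fam$reference)
      note("deduplicate_strains")
      assignment <- assign_one_to_one(dedup, fam$reference, fam$paralog)
      note("assign_one_to_one")

      partner_orgs <- dedup$organism[
        dedup$id %in% fam$truth$id[fam$truth$set == "partner_positive"]]
      partition <- partition_by_partner(assignment, partner_orgs)
      note("partition_by_partner")

      pick <- function(orgs) {
        recs <- dedup[dedup$id %in% partition$assigned[orgs], ]
        rbind(fam$reference[, c("id", "organism", "species_key", "sequence")],
              recs[, c("id", "organism", "species_key", "sequence")])
      }
      aln_pos <- msa_from_records(pick(partition$partner_positive))
      aln_neg <- msa_from_records(pick(partition$partner_negative))
      reference_id <- fam$reference$id[1]
      write_alignment(aln_pos, file.path(out_dir, "aln_partner_pos.fasta"))
      write_alignment(aln_neg, file.path(out_dir, "aln_partner_neg.fasta"))
      write_tsv_report(as.data.frame(assignment),
                       file.path(out_dir, "assignment.tsv"),
                       params = list(seed = config$sim$seed,
                                     note = "partner list treated as authoritative"))
      note("curate_outputs")

      ## truth scoring: every non-duplicate planted organism should be
      ## assigned its own planted sequence (or its strain's), never the decoy
      truth <- fam$truth
      sp_of_org <- stats::setNames(dedup$species_key, dedup$organism)
      assigned_ok <- vapply(seq_along(partition$assigned), function(k) {
        org <- names(partition$assigned)[k]
        id <- partition$assigned[[k]]
        id %in% truth$id[truth$species_key == sp_of_org[[org]]]
      }, logical(1))
      truth_recovery <- list(
        fraction_assigned = mean(assigned_ok),
        n_assigned = length(partition$assigned),
        n_species = length(unique(truth$species_key)),
        paralog_assigned = fam$paralog$id[1] %in% partition$assigned,
        partition_matches_truth = setequal(
          sp_of_org[partition$partner_positive],
          unique(truth$species_key[truth$set == "partner_positive"]))
      )
    } else {
      aln_pos <- read_alignment(config$aln_pos)
      aln_neg <- read_alignment(config$aln_neg)
      reference_id <- config$reference_id %||%
        abort("config$reference_id is required for pre-aligned input")
      region <- config$region %||% interface_region("ctr")
      note("read_alignments")
      assignment <- NULL; partition <- NULL; truth_recovery <- NULL
    }

    comparison <- compare_region(aln_pos, aln_neg, reference_id, region,
                                 params, n_perm, seed)
    note("compare_region")

    for (side in c("pos", "neg")) {
      prof <- comparison[[paste0("profile_", side)]]
      write_tsv_report(
        as.data.frame(prof), file.path(out_dir, sprintf("profile_%s.tsv", side)),
        params = list(reference = reference_id,
                      window_radius = params$window_radius,
                      window_weight = params$window_weight,
                      pseudocount = params$pseudocount,
                      sequence_weighting = params$use_sequence_weighting,
                      weighting_scheme = "position-based (standard choice; see docs)"))
    }
    write_tsv_report(as.data.frame(comparison$paired),
                     file.path(out_dir, "region_scores.tsv"),
                     params = list(region = region, n_perm = n_perm,
                                   seed = seed,
                                   delta_mean = comparison$delta_mean,
                                   permutation_p = comparison$permutation_p,
                                   signed_rank_p = comparison$signed_rank_p))
    note("write_reports")

    list(comparison = comparison, assignment = assignment,
         partition = partition, truth_recovery = truth_recovery,
         out_dir = out_dir)
  })
}

#' Run the expression directionality analysis
#'
#' Classifies the two conditions by regulator rules, intersects the
#' literature target list, and tests fold-change directionality.
#'
#' @param config list with: `sim` (a [de_sim_config()]) or (`table_a`,
#'   `table_b`, `label_a`, `label_b`, `targets` file paths); `rules`
#'   (list of two [regulator_rule()]s; defaults to AL1-high/PR3-low vs
#'   AL1-high/PR3-high); `direction_class` (default `"up"`);
#'   `min_class_size` (default 6); `out_dir`.
#' @return list: `report` (a `partition_report`), `classes` (condition
#'   labels assigned by the rules), `out_dir`.
#' @export
run_expression <- function(config) {
  out_dir <- config$out_dir %||% tempfile("expr_run_")
  rules <- config$rules %||% list(
    regulator_rule("AL1High_PR3Low", c("ALDH1A1", "PRMT3"), c("up", "down")),
    regulator_rule("AL1High_PR3High", c("ALDH1A1", "PRMT3"), c("up", "up")))
  min_class_size <- config$min_class_size %||% 6L
  direction_class <- config$direction_class %||% "up"

  run_with_manifest(out_dir, config, function(note) {
    if (!is.null(config$sim)) {
      sim <- simulate_de_tables(config$sim)
      table_a <- sim$table_a; table_b <- sim$table_b; targets <- sim$targets
      note("simulate")
    } else {
      table_a <- read_de_table(config$table_a, config$label_a %||% "A")
      table_b <- read_de_table(config$table_b, config$label_b %||% "B")
      targets <- read_target_list(config$targets)
      note("read_tables")
    }

    classes <- vapply(list(table_a, table_b), function(t) {
      hits <- vapply(rules, function(r) classify_condition(t, r)$matched,
                     logical(1))
      if (any(hits)) rules[[which(hits)[1]]]$label else "unclassified"
    }, character(1))
    note("classify_conditions")

    shared <- intersect_targets(list(table_a, table_b), targets,
                                direction_class, min_class_size)
    attr(shared, "condition_labels") <- classes
    note("intersect_targets")
    report <- directionality_analysis(shared)
    note("directionality_analysis")

    write_tsv_report(as.data.frame(report$per_gene),
                     file.path(out_dir, "per_gene_delta.tsv"),
                     params = list(
                       condition_a = classes[1], condition_b = classes[2],
                       n_shared = report$n_shared,
                       median_a = report$medians[1],
                       median_b = report$medians[2],
                       rank_sum_p = report$rank_sum$p_value,
                       fisher_p = report$fisher$p_value))
    note("write_reports")
    list(report = report, classes = classes, out_dir = out_dir)
  })
}

#' Run the enzyme-rate analysis
#'
#' @param config list with: `sim` (a [kinetics_sim_config()]) or
#'   `timecourse` (CSV path) plus optional `standard_curve` (CSV path with
#'   columns `conc_uM`, `reading`); `control` condition name; at most one of
#'   `window_points` / `window_time`; `out_dir`.
#' @return list: `rates` (per-replicate slopes), `result` (a `rate_result`),
#'   `out_dir`.
#' @export
run_rates <- function(config) {
  out_dir <- config$out_dir %||% tempfile("rates_run_")
  control <- config$control %||% "control"

  run_with_manifest(out_dir, config, function(note) {
    curve <- NULL
    if (!is.null(config$standard_curve)) {
      sc <- utils::read.csv(config$standard_curve, comment.char = "#")
      require_columns(sc, c("conc_uM", "reading"), config$standard_curve)
      curve <- fit_standard_curve(sc$conc_uM, sc$reading)
      note("fit_standard_curve")
    }
    if (!is.null(config$sim)) {
      tc <- simulate_timecourses(config$sim, standard_curve = curve)$timecourse
      note("simulate")
    } else {
      tc <- read_timecourse(config$timecourse,
                            config$reading_kind %||% "concentration")
      note("read_timecourse")
    }
    rates <- replicate_rates(tc, standard_curve = curve,
                             window_points = config$window_points %||% 6L,
                             window_time = config$window_time)
    note("replicate_rates")
    result <- summarize_rates(rates, control = control)
    note("summarize_rates")
    write_tsv_report(as.data.frame(result$summary),
                     file.path(out_dir, "rate_summary.tsv"),
                     params = list(control = control,
                                   window_points = config$window_points %||% 6L,
                                   spearman_rho = result$spearman_rho))
    note("write_reports")
    list(rates = rates, result = result, out_dir = out_dir)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
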