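## synthetic_data: generators with planted ground truth for every downstream
## stage. Defaults are the study conditions the analyses assume: ortholog
## families of 30 partner-positive + 30 partner-negative organisms over a
## 200-residue protein with a 30-residue interface region conserved only in
## the partner-positive set; DE tables with 33 shared RA targets at mean
## log2FC +2.5 / -2.6 (sd 1.5); linear NADH accumulation at 1 uM/min sampled
## every 2 min for 60 min with 0.2 uM noise, three replicates.

#' Configuration for ortholog-family simulation
#'
#' Each organism's sequence derives from a common reference by independent
#' per-site substitution: probability `p_sub_region_pos` inside `region` for
#' partner-positive organisms, `p_sub_region_neg` for partner-negative, and
#' `p_sub_background` elsewhere for both. Substituted residues are uniform
#' over the 19 alternatives (keeps the binomial oracle exact). Strain
#' duplicates share a species key with an existing organism; a decoy human
#' paralog diverges at `paralog_divergence`.
#'
#' @param reference_length protein length in residues.
#' @param n_partner_pos,n_partner_neg organism counts per set.
#' @param region inclusive 1-based residue interval `c(start, end)` of the
#'   planted interface.
#' @param p_sub_background,p_sub_region_pos,p_sub_region_neg per-site
#'   substitution probabilities in \[0, 1\].
#' @param n_strain_duplicates extra organisms sharing an existing species key.
#' @param paralog_divergence per-site substitution probability of the decoy
#'   paralog.
#' @param seed RNG seed for this generator call.
#' @return config list of class `msa_sim_config`.
#' @export
msa_sim_config <- function(reference_length = 200L,
                           n_partner_pos = 30L, n_partner_neg = 30L,
                           region = c(101L, 130L),
                           p_sub_background = 0.3,
                           p_sub_region_pos = 0.02,
                           p_sub_region_neg = 0.3,
                           n_strain_duplicates = 3L,
                           paralog_divergence = 0.5,
                           seed = 1L) {
  reference_length <- check_count(reference_length, "reference_length", 1L)
  n_partner_pos <- check_count(n_partner_pos, "n_partner_pos")
  n_partner_neg <- check_count(n_partner_neg, "n_partner_neg")
  if (length(region) != 2L || region[1] > region[2] ||
      region[1] < 1L || region[2] > reference_length) {
    abort("`region` must be c(start, end) within [1, reference_length]")
  }
  for (p in c("p_sub_background", "p_sub_region_pos", "p_sub_region_neg",
              "paralog_divergence")) {
    check_number(get(p), p, 0, 1)
  }
  n_strain_duplicates <- check_count(n_strain_duplicates,
                                     "n_strain_duplicates")
  structure(list(reference_length = reference_length,
                 n_partner_pos = n_partner_pos,
                 n_partner_neg = n_partner_neg,
                 region = as.integer(region),
                 p_sub_background = p_sub_background,
                 p_sub_region_pos = p_sub_region_pos,
                 p_sub_region_neg = p_sub_region_neg,
                 n_strain_duplicates = n_strain_duplicates,
                 paralog_divergence = paralog_divergence,
                 seed = as.integer(seed)),
            class = "msa_sim_config")
}

mutate_seq <- function(ref_codes, p_site) {
  hit <- stats::runif(length(ref_codes)) < p_site
  if (any(hit)) {
    ## uniform over the 19 alternatives to the current residue
    shift <- sample.int(19L, sum(hit), replace = TRUE)
    ref_codes[hit] <- ((ref_codes[hit] - 1L + shift) %% 20L) + 1L
  }
  ref_codes
}

#' Simulate ortholog sequence families with a planted conserved region
#'
#' @param cfg an [msa_sim_config()].
#' @return list with elements `reference` (the query record), `paralog`
#'   (decoy human paralog record), `partner_pos` / `partner_neg`
#'   (sequence-record tibbles, strain duplicates included), and `truth`
#'   (tibble recording, per generated sequence, its set, species key, and
#'   whether it is a strain duplicate; the config travels as an attribute).
#' @export
simulate_ortholog_families <- function(cfg = msa_sim_config()) {
  stopifnot(inherits(cfg, "msa_sim_config"))
  with_local_seed(cfg$seed, {
    L <- cfg$reference_length
    ref_codes <- sample.int(20L, L, replace = TRUE)
    in_region <- seq_len(L) >= cfg$region[1] & seq_len(L) <= cfg$region[2]

    make_set <- function(n, prefix, p_region) {
      p_site <- ifelse(in_region, p_region, cfg$p_sub_background)
      ids <- sprintf("%s%02d", prefix, seq_len(n))
      organisms <- sprintf("Genus%s%02d species%02d", prefix, seq_len(n),
                           seq_len(n))
      seqs <- vapply(seq_len(n),
                     function(i) decode_seq(mutate_seq(ref_codes, p_site)),
                     character(1))
      new_seq_records(ids, organisms, seqs)
    }

    pos <- make_set(cfg$n_partner_pos, "pos", cfg$p_sub_region_pos)
    neg <- make_set(cfg$n_partner_neg, "neg", cfg$p_sub_region_neg)

    truth <- tibble::tibble(
      id = c(pos$id, neg$id),
      species_key = c(pos$species_key, neg$species_key),
      set = rep(c("partner_positive", "partner_negative"),
                c(nrow(pos), nrow(neg))),
      strain_duplicate = FALSE
    )

    ## strain duplicates: resampled sequences sharing an existing organism's
    ## species key, distributed over both sets
    if (cfg$n_strain_duplicates > 0L) {
      hosts_pool <- rbind(cbind(pos, set = "partner_positive"),
                          cbind(neg, set = "partner_negative"))
      take <- ((seq_len(cfg$n_strain_duplicates) - 1L) %% nrow(hosts_pool)) + 1L
      for (k in seq_len(cfg$n_strain_duplicates)) {
        host <- hosts_pool[take[k], ]
        p_region <- if (host$set == "partner_positive") {
          cfg$p_sub_region_pos
        } else {
          cfg$p_sub_region_neg
        }
        p_site <- ifelse(in_region, p_region, cfg$p_sub_background)
        rec <- new_seq_records(
          sprintf("%s_strain%d", host$id, k),
          paste(host$organism, sprintf("strain %d", k)),
          decode_seq(mutate_seq(ref_codes, p_site)),
          species_key = host$species_key
        )
        if (host$set == "partner_positive") pos <- rbind(pos, rec)
        else neg <- rbind(neg, rec)
        truth <- rbind(truth, tibble::tibble(
          id = rec$id, species_key = rec$species_key, set = host$set,
          strain_duplicate = TRUE))
      }
    }

    reference <- new_seq_records("REF_QUERY", "Homo sapiens",
                                 decode_seq(ref_codes))
    paralog <- new_seq_records(
      "REF_PARALOG", "Homo sapiens",
      decode_seq(mutate_seq(ref_codes, cfg$paralog_divergence)))

    attr(truth, "config") <- cfg
    list(reference = reference, paralog = paralog,
         partner_pos = pos, partner_neg = neg, truth = truth)
  })
}

#' Configuration for differential-expression table simulation
#'
#' Shared targets receive log2 fold changes Normal(`mu_pos`, `sigma`) in
#' condition A and Normal(`mu_neg`, `sigma`) in condition B; background genes
#' are Normal(0, `sigma`) independently in each condition; regulator genes
#' are set exactly per `regulator_spec`. A small class of `n_targets_down`
#' literature down-targets is included so the downstream small-class
#' exclusion rule is exercised.
#'
#' @param n_targets_shared shared up-target count.
#' @param n_targets_down literature down-target count (default 5, the class
#'   the analysis excludes as too small).
#' @param n_background_genes background gene count.
#' @param mu_pos,mu_neg mean target log2FC in conditions A / B.
#' @param sigma log2FC standard deviation (> 0).
#' @param regulator_spec data frame with columns `gene`, `condition`
#'   (`"A"`/`"B"`), `log2fc`, `significant`.
#' @param seed RNG seed.
#' @return config list of class `de_sim_config`.
#' @export
de_sim_config <- function(n_targets_shared = 33L,
                          n_targets_down = 5L,
                          n_background_genes = 500L,
                          mu_pos = 2.5, mu_neg = -2.6, sigma = 1.5,
                          regulator_spec = NULL,
                          seed = 1L) {
  n_targets_shared <- check_count(n_targets_shared, "n_targets_shared")
  n_targets_down <- check_count(n_targets_down, "n_targets_down")
  n_background_genes <- check_count(n_background_genes, "n_background_genes")
  check_number(sigma, "sigma", min = 1e-12)
  check_number(mu_pos, "mu_pos")
  check_number(mu_neg, "mu_neg")
  if (is.null(regulator_spec)) {
    ## regulator fold changes mirror the two condition classes: ALDH1A1 up in
    ## both (log2FC 3.8 vs 1.4), PRMT3 down in A and up in B
    regulator_spec <- data.frame(
      gene = c("ALDH1A1", "PRMT3", "ALDH1A1", "PRMT3"),
      condition = c("A", "A", "B", "B"),
      log2fc = c(3.8, -1.5, 1.4, 1.2),
      significant = TRUE
    )
  }
  structure(list(n_targets_shared = n_targets_shared,
                 n_targets_down = n_targets_down,
                 n_background_genes = n_background_genes,
                 mu_pos = mu_pos, mu_neg = mu_neg, sigma = sigma,
                 regulator_spec = regulator_spec,
                 seed = as.integer(seed)),
            class = "de_sim_config")
}

#' Simulate paired differential-expression tables with planted directionality
#'
#' @param cfg a [de_sim_config()].
#' @return list with `table_a`, `table_b` (de_table tibbles, condition labels
#'   `"A"` / `"B"`), `targets` (target list: shared targets marked `up`, plus
#'   the small `down` class), and `truth` (per-gene planted means and roles).
#' @export
simulate_de_tables <- function(cfg = de_sim_config()) {
  stopifnot(inherits(cfg, "de_sim_config"))
  with_local_seed(cfg$seed, {
    up_genes <- sprintf("RATGT%03d", seq_len(cfg$n_targets_shared))
    down_genes <- if (cfg$n_targets_down > 0L) {
      sprintf("RADWN%03d", seq_len(cfg$n_targets_down))
    } else {
      character(0)
    }
    bg_genes <- if (cfg$n_background_genes > 0L) {
      sprintf("BG%04d", seq_len(cfg$n_background_genes))
    } else {
      character(0)
    }

    draw <- function(mu_up) {
      c(stats::rnorm(length(up_genes), mu_up, cfg$sigma),
        stats::rnorm(length(down_genes), -mu_up, cfg$sigma),
        stats::rnorm(length(bg_genes), 0, cfg$sigma))
    }
    genes <- c(up_genes, down_genes, bg_genes)
    lfc_a <- draw(cfg$mu_pos)
    lfc_b <- draw(cfg$mu_neg)

    build <- function(lfc, cond) {
      df <- data.frame(gene = genes, log2fc = lfc,
                       significant = rep(TRUE, length(genes)))
      spec <- cfg$regulator_spec[cfg$regulator_spec$condition == cond, ]
      df <- rbind(df, data.frame(gene = spec$gene, log2fc = spec$log2fc,
                                 significant = spec$significant))
      as_de_table(df, cond)
    }

    targets <- tibble::tibble(
      gene = c(up_genes, down_genes),
      direction = rep(c("up", "down"), c(length(up_genes), length(down_genes)))
    )
    truth <- tibble::tibble(
      gene = genes,
      role = rep(c("shared_up_target", "down_target", "background"),
                 c(length(up_genes), length(down_genes), length(bg_genes))),
      mu_a = c(rep(cfg$mu_pos, length(up_genes)),
               rep(-cfg$mu_pos, length(down_genes)),
               rep(0, length(bg_genes))),
      mu_b = c(rep(cfg$mu_neg, length(up_genes)),
               rep(-cfg$mu_neg, length(down_genes)),
               rep(0, length(bg_genes)))
    )
    attr(truth, "config") <- cfg
    list(table_a = build(lfc_a, "A"), table_b = build(lfc_b, "B"),
         targets = targets, truth = truth)
  })
}

#' Configuration for NADH time-course simulation
#'
#' Concentration follows `v_true * (1 - inhibition) * t` plus Gaussian noise,
#' the linear initial phase of an enzyme assay sampled at a fixed cadence.
#'
#' @param v_true uninhibited rate, uM/min.
#' @param noise_sd Gaussian measurement noise, uM.
#' @param duration total time, min.
#' @param interval sampling interval, min (paper-style cadence: 2 min).
#' @param inhibition_fraction named numeric vector: fractional rate reduction
#'   per condition, each in \[0, 1\] (0 = uninhibited control).
#' @param dose optional named numeric vector of inhibitor concentrations per
#'   condition (for dose-series monotonicity diagnostics).
#' @param n_replicates replicates per condition.
#' @param seed RNG seed.
#' @return config list of class `kinetics_sim_config`.
#' @export
kinetics_sim_config <- function(v_true = 1.0, noise_sd = 0.2,
                                duration = 60, interval = 2,
                                inhibition_fraction = c(control = 0,
                                                        treated = 0.3),
                                dose = NULL,
                                n_replicates = 3L, seed = 1L) {
  check_number(v_true, "v_true")
  check_number(noise_sd, "noise_sd", min = 0)
  check_number(interval, "interval", min = 1e-12)
  check_number(duration, "duration", min = 3 * interval)
  if (is.null(names(inhibition_fraction)) ||
      any(!nzchar(names(inhibition_fraction)))) {
    abort("`inhibition_fraction` must be a named vector (one name per condition)")
  }
  if (any(inhibition_fraction < 0 | inhibition_fraction > 1)) {
    abort("`inhibition_fraction` values must lie in [0, 1]")
  }
  if (!is.null(dose) && !identical(names(dose), names(inhibition_fraction))) {
    abort("`dose` names must match `inhibition_fraction` names")
  }
  n_replicates <- check_count(n_replicates, "n_replicates", 1L)
  structure(list(v_true = v_true, noise_sd = noise_sd, duration = duration,
                 interval = interval,
                 inhibition_fraction = inhibition_fraction, dose = dose,
                 n_replicates = n_replicates, seed = as.integer(seed)),
            class = "kinetics_sim_config")
}

#' Simulate NADH accumulation time courses
#'
#' @param cfg a [kinetics_sim_config()].
#' @param standard_curve optional [fit_standard_curve()] result; when given,
#'   concentrations are converted to absorbance readings through it and the
#'   output is flagged `reading_kind = "absorbance"`.
#' @return list with `timecourse` (a `timecourse` tibble) and `truth`
#'   (per-condition planted rates).
#' @export
simulate_timecourses <- function(cfg = kinetics_sim_config(),
                                 standard_curve = NULL) {
  stopifnot(inherits(cfg, "kinetics_sim_config"))
  with_local_seed(cfg$seed, {
    times <- seq(0, cfg$duration, by = cfg$interval)
    rows <- list()
    for (cond in names(cfg$inhibition_fraction)) {
      v <- cfg$v_true * (1 - cfg$inhibition_fraction[[cond]])
      for (r in seq_len(cfg$n_replicates)) {
        conc <- v * times + stats::rnorm(length(times), 0, cfg$noise_sd)
        reading <- if (is.null(standard_curve)) {
          conc
        } else {
          standard_curve$intercept + standard_curve$slope * conc
        }
        df <- data.frame(condition = cond, replicate = sprintf("rep%d", r),
                         time_min = times, reading = reading)
        if (!is.null(cfg$dose)) df$dose <- cfg$dose[[cond]]
        rows[[length(rows) + 1L]] <- df
      }
    }
    kind <- if (is.null(standard_curve)) "concentration" else "absorbance"
    tc <- as_timecourse(do.call(rbind, rows), kind)
    truth <- tibble::tibble(
      condition = names(cfg$inhibition_fraction),
      inhibition_fraction = unname(cfg$inhibition_fraction),
      true_rate = cfg$v_true * (1 - unname(cfg$inhibition_fraction))
    )
    attr(truth, "config") <- cfg
    list(timecourse = tc, truth = truth)
  })
}
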