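## ortholog_curation: strain hygiene, one-to-one ortholog assignment by
## pairwise identity against the query versus its human paralogs, and the
## partner presence/absence partition.

#' Keep one sequence per species
#'
#' Orthology databases often carry several strains of the same species; the
#' curation rule keeps, per species key, the record with the highest pairwise
#' identity to the query, breaking ties by longer sequence and then by
#' lexicographically smallest id.
#'
#' @param records sequence-record tibble with populated `species_key`.
#' @param query single-row sequence record (the reference protein).
#' @param matrix,gap_open,gap_extend alignment parameters, see
#'   [global_align()].
#' @return records with exactly one row per species key, with an `identity`
#'   column (identity to the query) attached.
#' @export
deduplicate_strains <- function(records, query, matrix = blosum62_matrix(),
                                gap_open = 11, gap_extend = 1) {
  if (nrow(records) == 0L) return(records)
  records$identity <- identities_to(records, query$sequence[1],
                                    matrix, gap_open, gap_extend)
  keep <- vapply(split(seq_len(nrow(records)), records$species_key),
                 function(idx) {
                   sub <- records[idx, ]
                   ord <- order(-sub$identity, -nchar(sub$sequence), sub$id)
                   idx[ord[1]]
                 }, integer(1))
  out <- records[sort(unname(keep)), ]
  rownames(out) <- NULL
  out
}

#' One-to-one ortholog assignment
#'
#' Per organism, the candidate with the highest identity to the query is the
#' putative ortholog; it is assigned as one-to-one only when its identity to
#' the query strictly exceeds its identity to every supplied query paralog
#' (otherwise the candidate is likelier a co-ortholog of the paralog and is
#' rejected with reason `paralog_closer`).
#'
#' @param candidates sequence-record tibble; the `organism` column defines
#'   the assignment unit.
#' @param query single-row record of the reference protein.
#' @param paralogs sequence-record tibble of the query's within-proteome
#'   paralogs (may be empty).
#' @inheritParams deduplicate_strains
#' @return tibble with one row per organism: `organism`, `id` (NA when
#'   rejected), `identity_query`, `identity_best_paralog`, `reason`
#'   (`assigned`, `paralog_closer`, or `no_candidate`).
#' @export
assign_one_to_one <- function(candidates, query, paralogs = NULL,
                              matrix = blosum62_matrix(),
                              gap_open = 11, gap_extend = 1) {
  organisms <- sort(unique(candidates$organism))
  if (length(organisms) == 0L) abort("no candidate sequences supplied")
  id_query <- identities_to(candidates, query$sequence[1],
                            matrix, gap_open, gap_extend)
  rows <- lapply(organisms, function(org) {
    idx <- which(candidates$organism == org)
    if (length(idx) == 0L) {
      return(tibble::tibble(organism = org, id = NA_character_,
                            identity_query = NA_real_,
                            identity_best_paralog = NA_real_,
                            reason = "no_candidate"))
    }
    ord <- idx[order(-id_query[idx], candidates$id[idx])]
    best <- ord[1]
    iq <- id_query[best]
    ip <- 0
    if (!is.null(paralogs) && nrow(paralogs) > 0L) {
      ip <- max(vapply(paralogs$sequence, function(p) {
        global_align(candidates$sequence[best], p,
                     matrix, gap_open, gap_extend)$identity
      }, numeric(1)))
    }
    if (iq > ip) {
      tibble::tibble(organism = org, id = candidates$id[best],
                     identity_query = iq, identity_best_paralog = ip,
                     reason = "assigned")
    } else {
      tibble::tibble(organism = org, id = NA_character_,
                     identity_query = iq, identity_best_paralog = ip,
                     reason = "paralog_closer")
    }
  })
  do.call(rbind, rows)
}

#' Partition assigned organisms by partner presence
#'
#' Splits organisms carrying an assigned one-to-one ortholog of the query
#' into those that also possess the interaction partner (partner-positive)
#' and those that do not. The partner-organism list is taken as authoritative
#' (absence of the partner from it is treated as true absence, not missed
#' detection); this assumption is recorded in emitted report headers.
#'
#' @param assignment output of [assign_one_to_one()].
#' @param partner_organisms character vector of organisms possessing the
#'   partner protein.
#' @return list of class `partition_result`: `assigned` (organism -> id for
#'   assigned rows), `partner_positive`, `partner_negative` (organism
#'   vectors), `rejected` (tibble organism/reason).
#' @export
partition_by_partner <- function(assignment, partner_organisms) {
  ok <- assignment$reason == "assigned"
  if (!any(ok)) abort("no assigned organisms to partition")
  assigned <- stats::setNames(assignment$id[ok], assignment$organism[ok])
  pos <- names(assigned)[names(assigned) %in% partner_organisms]
  neg <- setdiff(names(assigned), pos)
  if (length(pos) == 0L || length(neg) == 0L) {
    abort("degenerate partition: one partner set is empty, comparison impossible",
          class = "coevkit_degenerate_partition")
  }
  structure(list(assigned = assigned,
                 partner_positive = pos, partner_negative = neg,
                 rejected = tibble::tibble(
                   organism = assignment$organism[!ok],
                   reason = assignment$reason[!ok])),
            class = "partition_result")
}

#' @export
print.partition_result <- function(x, ...) {
  cat(sprintf("<partition_result> %d assigned (%d partner+, %d partner-), %d rejected\n",
              length(x$assigned), length(x$partner_positive),
              length(x$partner_negative), nrow(x$rejected)))
  invisible(x)
}
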