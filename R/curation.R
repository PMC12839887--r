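## Dataset curation for the quinone redox-potential collection: 350 records
## indexed 000-349 (117 substituted 1,4-benzoquinones, 90 naphthoquinones,
## 110 anthraquinones, 33 miscellaneous/non-quinones).  Three records are
## excluded: index 116, whose structure cannot be determined from its name,
## and indices 209/210, duplicates of 192/193.

.CURATION_EXCLUSIONS <- c("116", "209", "210")

#' Build the full 000-349 index roster
#'
#' Deterministic synthetic roster carrying the published family sizes and
#' availability flags; per-molecule labels are placeholders (the roster is
#' for exercising curation, not a data source).  Q2 availability: the last
#' `n_q2_missing` retained indices are marked as lacking Q2.
#'
#' @param n_q2_missing number of retained molecules without a Q2 value
#'   (default 80, as reported for the source collection).
#' @return data frame with `molecule_id`, `family`, `q1_mv`, `q2_mv`,
#'   `sigma_p` columns (labels NA where unavailable, 0-placeholders
#'   otherwise are not used: available labels carry a deterministic dummy
#'   value derived from the index).
#' @export
quinone_index_roster <- function(n_q2_missing = 80L) {
  id <- sprintf("%03d", 0:349)
  family <- c(rep("BQ", 117), rep("NQ", 90), rep("AQ", 110),
              rep("misc", 33))
  q1 <- -1000 + 5 * (0:349)  # deterministic placeholder potentials, mV
  q2 <- q1 - 700
  roster <- data.frame(molecule_id = id, family = family,
                       q1_mv = q1, q2_mv = q2,
                       sigma_p = NA_real_, stringsAsFactors = FALSE)
  retained <- !(roster$molecule_id %in% .CURATION_EXCLUSIONS)
  ret_idx <- which(retained)
  if (n_q2_missing > 0) {
    drop_q2 <- utils::tail(ret_idx, n_q2_missing)
    roster$q2_mv[drop_q2] <- NA_real_
  }
  roster
}

#' Curate a raw record table
#'
#' Applies the published exclusion rules (drop index 116 and the duplicate
#' pair 209/210) and reports retained label counts.
#'
#' @param records data frame with at least `molecule_id`, `q1_mv`, `q2_mv`
#'   columns.
#' @return list with `table` (curated records), `n_q1` (retained rows with
#'   a Q1 value), `n_q2` (retained rows with a Q2 value), and `excluded`
#'   (ids dropped).
#' @export
curate_dataset <- function(records) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0) {
    return(list(table = records, n_q1 = 0L, n_q2 = 0L,
                excluded = character(0)))
  }
  if (!"molecule_id" %in% names(records)) {
    stop("records must carry a molecule_id column")
  }
  if (anyDuplicated(records$molecule_id)) {
    stop("duplicate molecule_id in input: ",
         paste(unique(records$molecule_id[duplicated(records$molecule_id)]),
               collapse = ", "))
  }
  drop <- records$molecule_id %in% .CURATION_EXCLUSIONS
  out <- records[!drop, , drop = FALSE]
  rownames(out) <- NULL
  n_q1 <- if ("q1_mv" %in% names(out)) sum(!is.na(out$q1_mv)) else 0L
  n_q2 <- if ("q2_mv" %in% names(out)) sum(!is.na(out$q2_mv)) else 0L
  list(table = out, n_q1 = as.integer(n_q1), n_q2 = as.integer(n_q2),
       excluded = records$molecule_id[drop])
}
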