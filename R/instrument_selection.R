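#' Construct a pairwise LD matrix
#'
#' @param ids Character vector of variant ids (defines the order).
#' @param r2 Square numeric matrix of squared allelic correlations, one
#'   row/column per id. Must be symmetric with a unit diagonal and all
#'   entries in \[0, 1\].
#' @return An object of class `ld_matrix`: a list with elements `ids` and
#'   `r2` (dimnames set to `ids`).
#' @export
ld_matrix <- function(ids, r2) {
  ids <- as.character(ids)
  r2 <- as.matrix(r2)
  if (nrow(r2) != length(ids) || ncol(r2) != length(ids))
    stop("r2 must be a ", length(ids), "x", length(ids), " matrix", call. = FALSE)
  if (any(is.na(r2)) || any(r2 < 0) || any(r2 > 1))
    stop("r2 entries must lie in [0, 1]", call. = FALSE)
  if (max(abs(r2 - t(r2))) > 1e-12) stop("r2 must be symmetric", call. = FALSE)
  if (any(abs(diag(r2) - 1) > 1e-12)) stop("r2 diagonal must be 1", call. = FALSE)
  dimnames(r2) <- list(ids, ids)
  structure(list(ids = ids, r2 = r2), class = "ld_matrix")
}

#' Read a pairwise LD table
#'
#' Accepts either a long-format TSV with columns `id_a`, `id_b`, `r2`
#' (unlisted pairs default to r² = 0) or a square-matrix TSV whose first
#' column holds variant ids matching the remaining column headers.
#'
#' @param path Path to the TSV file.
#' @return An [ld_matrix()] object.
#' @export
read_ld <- function(path) {
  if (!file.exists(path)) stop("LD file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           fileEncoding = "UTF-8")
  if (all(c("id_a", "id_b", "r2") %in% names(raw))) {
    ids <- unique(c(as.character(raw$id_a), as.character(raw$id_b)))
    m <- diag(1, length(ids))
    dimnames(m) <- list(ids, ids)
    for (i in seq_len(nrow(raw))) {
      a <- as.character(raw$id_a[i]); b <- as.character(raw$id_b[i])
      m[a, b] <- m[b, a] <- as.numeric(raw$r2[i])
    }
    diag(m) <- 1
    return(ld_matrix(ids, m))
  }
  ids <- as.character(raw[[1]])
  m <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (!identical(colnames(m), ids))
    stop("square LD table: column headers must match the id column", call. = FALSE)
  ld_matrix(ids, m)
}

#' Greedy LD pruning of candidate instruments
#'
#' Candidates are ranked by ascending exposure p-value (ties broken by
#' lexicographic variant id) and accepted greedily: a candidate is kept iff
#' its r² with every already-kept candidate is below `r2_max`. The rule is
#' deterministic, keeps the strongest instrument of every correlated clique,
#' and its kept set can only grow as `r2_max` is relaxed.
#'
#' @param variants `harmonized_variants` data frame (needs `variant_id` and
#'   `p_exposure`).
#' @param ld [ld_matrix()] covering every candidate id.
#' @param r2_max Exclusion threshold on r²; pairs at or above it may not
#'   coexist. Default 0.2.
#' @return Character vector of kept variant ids.
#' @export
ld_prune <- function(variants, ld, r2_max = 0.2) {
  ids <- variants$variant_id
  if (length(ids) == 0L) return(character(0))
  missing_ids <- setdiff(ids, ld$ids)
  if (length(missing_ids) > 0L)
    stop("LD matrix does not cover candidate id(s): ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  ord <- order(variants$p_exposure, ids)
  kept <- character(0)
  for (id in ids[ord]) {
    if (length(kept) == 0L || all(ld$r2[id, kept] < r2_max)) kept <- c(kept, id)
  }
  ids[ids %in% kept]  # restore input order
}

#' Select instrumental variants
#'
#' Applies the three instrument filters in order: (1) exposure genome-wide
#' significance, keeping variants with exposure p-value strictly below
#' `p_exposure_max`; (2) outcome-association exclusion, removing variants
#' with outcome p-value strictly below `p_outcome_min` (such variants may
#' act on the outcome through a path other than the exposure); (3) greedy LD
#' pruning via [ld_prune()] when an LD matrix is supplied. Every input
#' variant lands either in the kept set or in the exclusion log, never both.
#'
#' @param variants `harmonized_variants` data frame.
#' @param p_exposure_max Exposure significance threshold, default `5e-8`.
#' @param p_outcome_min Outcome-association removal threshold, default
#'   `0.05`: variants with `p_outcome < p_outcome_min` are removed.
#' @param ld Optional [ld_matrix()]; when `NULL`, pruning is skipped with a
#'   message.
#' @param r2_max LD pruning threshold, default 0.2.
#' @return List with elements `kept` (a `harmonized_variants` data frame)
#'   and `log` (data frame `variant_id`, `reason`, `detail`; reasons are
#'   `exposure_not_significant`, `outcome_associated`, `ld_pruned`).
#' @export
#' @examples
#' h <- read_paired_summary_stats(crp_fixture_path("crp_t2dm"))
#' sel <- select_instruments(h)
#' sel$log    # rs4420638 removed: outcome-associated
#' nrow(sel$kept)
select_instruments <- function(variants, p_exposure_max = 5e-8,
                               p_outcome_min = 0.05, ld = NULL, r2_max = 0.2) {
  stopifnot(p_exposure_max > 0, p_exposure_max < 1,
            p_outcome_min > 0, p_outcome_min < 1)
  log <- data.frame(variant_id = character(0), reason = character(0),
                    detail = character(0), stringsAsFactors = FALSE)
  add_log <- function(ids, reason, detail) {
    if (length(ids) > 0L)
      rbind(log, data.frame(variant_id = ids, reason = reason, detail = detail,
                            stringsAsFactors = FALSE))
    else log
  }
  fail1 <- variants$p_exposure >= p_exposure_max
  log <- add_log(variants$variant_id[fail1], "exposure_not_significant",
                 sprintf("p_exposure = %.3g", variants$p_exposure[fail1]))
  cand <- variants[!fail1, , drop = FALSE]

  fail2 <- cand$p_outcome < p_outcome_min
  log <- add_log(cand$variant_id[fail2], "outcome_associated",
                 sprintf("p_outcome = %.3g", cand$p_outcome[fail2]))
  cand <- cand[!fail2, , drop = FALSE]

  if (!is.null(ld)) {
    kept_ids <- ld_prune(cand, ld, r2_max)
    pruned <- setdiff(cand$variant_id, kept_ids)
    if (length(pruned) > 0L) {
      detail <- vapply(pruned, function(id) {
        r <- ld$r2[id, kept_ids, drop = TRUE]
        sprintf("r2 = %.3g with %s", max(r), kept_ids[which.max(r)])
      }, "")
      log <- add_log(pruned, "ld_pruned", detail)
    }
    cand <- cand[cand$variant_id %in% kept_ids, , drop = FALSE]
  } else {
    message("no LD matrix supplied; LD pruning skipped")
  }
  rownames(cand) <- NULL
  class(cand) <- c("harmonized_variants", "data.frame")
  list(kept = cand, log = log)
}

#' Write an exclusion log
#'
#' @param log Exclusion data frame from [select_instruments()] or the
#'   `"dropped"` attribute of [harmonize_tables()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_exclusion_log <- function(log, path) {
  utils::write.table(log, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
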