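#' Default column dialect for GWAS summary-statistic files
#'
#' Maps the canonical field names used throughout the package to the column
#' headers expected in an input file. Supply a modified copy to
#' [read_summary_stats()] when a file uses different headers.
#'
#' @return Named character vector: names are canonical fields
#'   (`variant_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`,
#'   `beta`, `se`, `pvalue`), values are the file's column headers.
#' @export
#' @examples
#' d <- default_dialect()
#' d["pvalue"] <- "p"  # file calls the p-value column "p"
default_dialect <- function() {
  c(variant_id = "snp", chrom = "chr", pos = "bp",
    effect_allele = "effect_allele", other_allele = "other_allele",
    eaf = "eaf", beta = "beta", se = "se", pvalue = "pvalue")
}

.required_fields <- c("variant_id", "chrom", "pos", "effect_allele",
                      "other_allele", "eaf", "beta", "se", "pvalue")

.parse_numeric <- function(x, column, path) {
  x[x %in% c(".", "", "NA")] <- NA_character_
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad) > 0L) {
    stop(sprintf("unparseable numeric field '%s' in %s at row(s) %s (value(s): %s)",
                 column, path, paste(bad, collapse = ", "),
                 paste(x[bad], collapse = ", ")), call. = FALSE)
  }
  out
}

#' Validate variant association records
#'
#' Checks the per-variant invariants: positive standard error, finite beta,
#' p-value in (0, 1], distinct single-nucleotide alleles, and (when present)
#' effect-allele frequency strictly inside (0, 1).
#'
#' @param x Data frame with the canonical columns of [read_summary_stats()].
#' @return Character vector of violation messages, one per offending row;
#'   empty when all rows are valid. Messages carry the 1-based row index.
#' @keywords internal
validate_variant_associations <- function(x) {
  msgs <- character(0)
  nuc <- c("A", "C", "G", "T")
  for (i in seq_len(nrow(x))) {
    problems <- character(0)
    if (is.na(x$se[i]) || x$se[i] <= 0) problems <- c(problems, "se must be > 0")
    if (is.na(x$beta[i]) || !is.finite(x$beta[i])) problems <- c(problems, "beta must be finite")
    if (is.na(x$pvalue[i]) || x$pvalue[i] <= 0 || x$pvalue[i] > 1)
      problems <- c(problems, "pvalue must be in (0,1]")
    if (!(x$effect_allele[i] %in% nuc) || !(x$other_allele[i] %in% nuc))
      problems <- c(problems, "alleles must be single nucleotides A/C/G/T")
    else if (x$effect_allele[i] == x$other_allele[i])
      problems <- c(problems, "effect_allele equals other_allele")
    if (!is.na(x$eaf[i]) && (x$eaf[i] <= 0 || x$eaf[i] >= 1))
      problems <- c(problems, "eaf must be in (0,1)")
    if (length(problems) > 0L) {
      msgs <- c(msgs, sprintf("row %d (%s): %s", i,
                              if (is.na(x$variant_id[i])) "?" else x$variant_id[i],
                              paste(problems, collapse = "; ")))
    }
  }
  msgs
}

#' Read GWAS summary statistics
#'
#' Reads a tab-separated summary-statistic table (header row, UTF-8, `.` or
#' empty for missing values) into a validated data frame of per-variant
#' associations, one row per variant, input order preserved. Rows violating
#' the record invariants (non-positive SE, p-value outside (0,1], identical
#' or non-ACGT alleles, frequency outside (0,1)) are dropped with a
#' row-numbered warning; an unparseable numeric field is an error.
#'
#' @param path Path to a TSV file.
#' @param dialect Named character vector mapping canonical field names to the
#'   file's column headers; see [default_dialect()].
#' @return Data frame of class `variant_assoc` with columns `variant_id`,
#'   `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`,
#'   `pvalue`. `eaf` may be `NA`; no estimator here uses it.
#' @export
#' @examples
#' crp <- read_summary_stats(system.file("extdata", "crp_gwas.tsv", package = "crpmr"))
#' head(crp)
read_summary_stats <- function(path, dialect = default_dialect()) {
  if (!file.exists(path)) stop("summary-statistic file not found: ", path, call. = FALSE)
  missing_fields <- setdiff(.required_fields, names(dialect))
  if (length(missing_fields) > 0L)
    stop("dialect does not map required field(s): ",
         paste(missing_fields, collapse = ", "), call. = FALSE)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           na.strings = character(0), fileEncoding = "UTF-8")
  absent <- setdiff(unname(dialect[.required_fields]), names(raw))
  if (length(absent) > 0L)
    stop("missing required column(s) in ", path, ": ",
         paste(absent, collapse = ", "), call. = FALSE)
  out <- data.frame(
    variant_id    = raw[[dialect[["variant_id"]]]],
    chrom         = raw[[dialect[["chrom"]]]],
    pos           = .parse_numeric(raw[[dialect[["pos"]]]], dialect[["pos"]], path),
    effect_allele = toupper(raw[[dialect[["effect_allele"]]]]),
    other_allele  = toupper(raw[[dialect[["other_allele"]]]]),
    eaf           = .parse_numeric(raw[[dialect[["eaf"]]]], dialect[["eaf"]], path),
    beta          = .parse_numeric(raw[[dialect[["beta"]]]], dialect[["beta"]], path),
    se            = .parse_numeric(raw[[dialect[["se"]]]], dialect[["se"]], path),
    pvalue        = .parse_numeric(raw[[dialect[["pvalue"]]]], dialect[["pvalue"]], path),
    stringsAsFactors = FALSE
  )
  msgs <- validate_variant_associations(out)
  if (length(msgs) > 0L) {
    bad_rows <- as.integer(sub("^row (\\d+).*$", "\\1", msgs))
    warning(sprintf("%s: rejected %d row(s):\n  %s", path, length(bad_rows),
                    paste(msgs, collapse = "\n  ")), call. = FALSE)
    out <- out[-bad_rows, , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("variant_assoc", "data.frame")
  out
}

#' Write GWAS summary statistics
#'
#' Inverse of [read_summary_stats()]: emits the default tab-separated dialect
#' with `.` for missing values. Numeric fields are written with 17 significant
#' digits so that a read/write round trip reproduces every double bit for bit.
#'
#' @param x Data frame with the canonical columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(x, path) {
  fmt <- function(v) {
    out <- vapply(v, function(z) if (is.na(z)) "." else sprintf("%.17g", z), "")
    out
  }
  tab <- data.frame(
    snp = x$variant_id, chr = x$chrom,
    bp = vapply(x$pos, function(z) if (is.na(z)) "." else sprintf("%d", as.integer(z)), ""),
    effect_allele = x$effect_allele, other_allele = x$other_allele,
    eaf = fmt(x$eaf), beta = fmt(x$beta), se = fmt(x$se), pvalue = fmt(x$pvalue),
    stringsAsFactors = FALSE
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

.is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

.harmonized_cols <- c("variant_id", "effect_allele", "other_allele",
                      "beta_exposure", "se_exposure", "p_exposure",
                      "beta_outcome", "se_outcome", "p_outcome", "flipped")

.empty_harmonized <- function() {
  out <- data.frame(variant_id = character(0), effect_allele = character(0),
                    other_allele = character(0), beta_exposure = numeric(0),
                    se_exposure = numeric(0), p_exposure = numeric(0),
                    beta_outcome = numeric(0), se_outcome = numeric(0),
                    p_outcome = numeric(0), flipped = logical(0),
                    stringsAsFactors = FALSE)
  class(out) <- c("harmonized_variants", "data.frame")
  out
}

#' Harmonize one variant's exposure and outcome associations
#'
#' Aligns the outcome association to the exposure's effect allele. When the
#' outcome lists the same allele pair in the same orientation the betas are
#' copied unchanged; when the pair is swapped the outcome beta is negated
#' (and its frequency complemented) and `flipped` is set. Palindromic
#' variants (A/T or C/G), whose strand cannot be resolved from alleles alone,
#' are handled per `palindrome_policy`.
#'
#' @param exposure,outcome One-row data frames in the canonical
#'   [read_summary_stats()] layout, same `variant_id`.
#' @param palindrome_policy `"keep"` (default; keep with a warning),
#'   `"drop"` (return an empty result), or `"error"`.
#' @return One-row data frame of class `harmonized_variants` with columns
#'   `variant_id`, `effect_allele`, `other_allele`, `beta_exposure`,
#'   `se_exposure`, `p_exposure`, `beta_outcome`, `se_outcome`, `p_outcome`,
#'   `flipped` (zero rows when a palindromic variant is dropped).
#' @export
harmonize <- function(exposure, outcome, palindrome_policy = c("keep", "drop", "error")) {
  palindrome_policy <- match.arg(palindrome_policy)
  if (nrow(exposure) != 1L || nrow(outcome) != 1L)
    stop("harmonize() aligns a single variant; use harmonize_tables() for collections",
         call. = FALSE)
  if (exposure$variant_id != outcome$variant_id)
    stop(sprintf("variant_id mismatch: exposure %s vs outcome %s",
                 exposure$variant_id, outcome$variant_id), call. = FALSE)
  pal <- .is_palindromic(exposure$effect_allele, exposure$other_allele)
  if (pal) {
    if (palindrome_policy == "error")
      stop("palindromic variant ", exposure$variant_id,
           " (", exposure$effect_allele, "/", exposure$other_allele, ")", call. = FALSE)
    if (palindrome_policy == "drop") return(.empty_harmonized())
    warning("palindromic variant ", exposure$variant_id,
            " kept without strand check", call. = FALSE)
  }
  same <- outcome$effect_allele == exposure$effect_allele &&
    outcome$other_allele == exposure$other_allele
  swapped <- outcome$effect_allele == exposure$other_allele &&
    outcome$other_allele == exposure$effect_allele
  if (!same && !swapped)
    stop(sprintf("incompatible allele sets for %s: exposure %s/%s vs outcome %s/%s",
                 exposure$variant_id, exposure$effect_allele, exposure$other_allele,
                 outcome$effect_allele, outcome$other_allele), call. = FALSE)
  out <- data.frame(
    variant_id = exposure$variant_id,
    effect_allele = exposure$effect_allele,
    other_allele = exposure$other_allele,
    beta_exposure = exposure$beta, se_exposure = exposure$se,
    p_exposure = exposure$pvalue,
    beta_outcome = if (swapped) -outcome$beta else outcome$beta,
    se_outcome = outcome$se, p_outcome = outcome$pvalue,
    flipped = swapped,
    stringsAsFactors = FALSE
  )
  class(out) <- c("harmonized_variants", "data.frame")
  out
}

#' Harmonize two summary-statistic tables
#'
#' Applies [harmonize()] to every variant shared by the exposure and outcome
#' tables, preserving exposure order. Variants present in only one table are
#' excluded (not an error) and listed in the `"dropped"` attribute of the
#' result, a data frame with columns `variant_id`, `reason`, `detail`.
#'
#' @inheritParams harmonize
#' @param exposure,outcome Data frames in the canonical layout.
#' @return Data frame of class `harmonized_variants` (see [harmonize()]),
#'   with attribute `"dropped"` recording one-sided or dropped-palindromic
#'   variants.
#' @export
#' @examples
#' exp <- read_summary_stats(system.file("extdata", "crp_gwas.tsv", package = "crpmr"))
#' out <- read_summary_stats(system.file("extdata", "t1dm_gwas.tsv", package = "crpmr"))
#' h <- harmonize_tables(exp, out)
#' nrow(h)            # 3 shared variants
#' attr(h, "dropped") # 2 CRP variants absent from the T1DM table
harmonize_tables <- function(exposure, outcome,
                             palindrome_policy = c("keep", "drop", "error")) {
  palindrome_policy <- match.arg(palindrome_policy)
  dropped <- data.frame(variant_id = character(0), reason = character(0),
                        detail = character(0), stringsAsFactors = FALSE)
  one_sided <- c(setdiff(exposure$variant_id, outcome$variant_id),
                 setdiff(outcome$variant_id, exposure$variant_id))
  if (length(one_sided) > 0L) {
    side <- ifelse(one_sided %in% exposure$variant_id,
                   "absent from outcome table", "absent from exposure table")
    dropped <- rbind(dropped, data.frame(variant_id = one_sided,
                                         reason = "unharmonizable",
                                         detail = side, stringsAsFactors = FALSE))
    message("excluded ", length(one_sided),
            " variant(s) present in only one table: ",
            paste(one_sided, collapse = ", "))
  }
  e <- exposure[exposure$variant_id %in% outcome$variant_id, , drop = FALSE]
  o <- outcome[match(e$variant_id, outcome$variant_id), , drop = FALSE]

  pal <- .is_palindromic(e$effect_allele, e$other_allele)
  if (any(pal)) {
    if (palindrome_policy == "error")
      stop("palindromic variant(s): ",
           paste(e$variant_id[pal], collapse = ", "), call. = FALSE)
    if (palindrome_policy == "drop") {
      dropped <- rbind(dropped, data.frame(
        variant_id = e$variant_id[pal], reason = "unharmonizable",
        detail = "palindromic, dropped by policy", stringsAsFactors = FALSE))
      e <- e[!pal, , drop = FALSE]; o <- o[!pal, , drop = FALSE]
    } else {
      warning("palindromic variant(s) kept without strand check: ",
              paste(e$variant_id[pal], collapse = ", "), call. = FALSE)
    }
  }
  same <- o$effect_allele == e$effect_allele & o$other_allele == e$other_allele
  swapped <- o$effect_allele == e$other_allele & o$other_allele == e$effect_allele
  incompatible <- !same & !swapped
  if (any(incompatible)) {
    dropped <- rbind(dropped, data.frame(
      variant_id = e$variant_id[incompatible], reason = "unharmonizable",
      detail = sprintf("incompatible alleles: exposure %s/%s vs outcome %s/%s",
                       e$effect_allele[incompatible], e$other_allele[incompatible],
                       o$effect_allele[incompatible], o$other_allele[incompatible]),
      stringsAsFactors = FALSE))
    message("excluded ", sum(incompatible),
            " variant(s) with incompatible allele sets: ",
            paste(e$variant_id[incompatible], collapse = ", "))
    e <- e[!incompatible, , drop = FALSE]
    o <- o[!incompatible, , drop = FALSE]
    swapped <- swapped[!incompatible]
  }
  out <- if (nrow(e) > 0L) {
    data.frame(
      variant_id = e$variant_id,
      effect_allele = e$effect_allele, other_allele = e$other_allele,
      beta_exposure = e$beta, se_exposure = e$se, p_exposure = e$pvalue,
      beta_outcome = ifelse(swapped, -o$beta, o$beta),
      se_outcome = o$se, p_outcome = o$pvalue,
      flipped = swapped, stringsAsFactors = FALSE
    )
  } else .empty_harmonized()
  rownames(out) <- NULL
  class(out) <- c("harmonized_variants", "data.frame")
  attr(out, "dropped") <- dropped
  out
}

#' Read a combined exposure/outcome instrument table
#'
#' Reads a table that lists, for each variant, both the exposure and the
#' outcome association on a shared effect allele (the layout of the packaged
#' `crp_t2dm.tsv` and `crp_t1dm.tsv` fixtures: columns `snp`, `chr`, `bp`,
#' `effect_allele`, `other_allele`, `eaf`, then `beta`/`se`/`p` suffixed
#' `_exposure` and `_outcome`).
#'
#' @param path Path to the combined TSV.
#' @return Data frame of class `harmonized_variants` with `flipped = FALSE`
#'   for every row (the table is pre-aligned).
#' @export
#' @examples
#' h <- read_paired_summary_stats(
#'   system.file("extdata", "crp_t2dm.tsv", package = "crpmr"))
read_paired_summary_stats <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", fileEncoding = "UTF-8")
  need <- c("snp", "effect_allele", "other_allele",
            "beta_exposure", "se_exposure", "p_exposure",
            "beta_outcome", "se_outcome", "p_outcome")
  absent <- setdiff(need, names(raw))
  if (length(absent) > 0L)
    stop("missing required column(s) in ", path, ": ",
         paste(absent, collapse = ", "), call. = FALSE)
  out <- data.frame(
    variant_id = as.character(raw$snp),
    effect_allele = toupper(as.character(raw$effect_allele)),
    other_allele = toupper(as.character(raw$other_allele)),
    beta_exposure = as.numeric(raw$beta_exposure),
    se_exposure = as.numeric(raw$se_exposure),
    p_exposure = as.numeric(raw$p_exposure),
    beta_outcome = as.numeric(raw$beta_outcome),
    se_outcome = as.numeric(raw$se_outcome),
    p_outcome = as.numeric(raw$p_outcome),
    flipped = FALSE, stringsAsFactors = FALSE
  )
  class(out) <- c("harmonized_variants", "data.frame")
  out
}

#' Path to a packaged CRP instrument fixture
#'
#' The package ships the published CRP instrument data as plain-text TSVs:
#' `"crp_t2dm"` and `"crp_t1dm"` are combined exposure+outcome tables (for
#' [read_paired_summary_stats()]); `"crp_gwas"`, `"t2dm_gwas"` and
#' `"t1dm_gwas"` are single-trait tables in the [read_summary_stats()]
#' dialect.
#'
#' @param name One of `"crp_t2dm"`, `"crp_t1dm"`, `"crp_gwas"`,
#'   `"t2dm_gwas"`, `"t1dm_gwas"`.
#' @return Absolute path to the installed fixture.
#' @export
crp_fixture_path <- function(name = c("crp_t2dm", "crp_t1dm", "crp_gwas",
                                      "t2dm_gwas", "t1dm_gwas")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".tsv"), package = "crpmr")
  if (!nzchar(path)) stop("fixture not found: ", name, call. = FALSE)
  path
}
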