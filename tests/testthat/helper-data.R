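# Published CRP instrument associations, entered independently of the
# shipped extdata fixtures so the tests cross-check the parsers.

table1 <- data.frame(
  variant_id = c("rs6700896", "rs4537545", "rs7553007", "rs1183910", "rs4420638"),
  chrom = c("1", "1", "1", "12", "19"),
  pos = c(65862370, 152685503, 157965173, 119905190, 50114786),
  effect_allele = c("T", "T", "A", "T", "G"),
  other_allele = c("C", "C", "G", "C", "A"),
  eaf = c(0.38, 0.43, 0.33, 0.32, 0.19),
  beta_exposure = c(-0.147, -0.108, -0.207, -0.136, -0.218),
  se_exposure = c(0.01429, 0.01531, 0.01429, 0.01429, 0.01837),
  p_exposure = c(1.6e-21, 5.1e-11, 3.3e-38, 1.2e-17, 2.1e-25),
  beta_outcome = c(-0.00995, -0.01980, -0.01980, 0.02956, -0.11333),
  se_outcome = c(0.01493, 0.00991, 0.01479, 0.00981, 0.02228),
  p_outcome = c(0.41, 0.21, 0.14, 0.059, 2.0e-7),
  stringsAsFactors = FALSE
)

table2 <- data.frame(
  variant_id = c("rs6700896", "rs7553007", "rs1183910"),
  chrom = c("1", "1", "12"),
  pos = c(65862370, 157965173, 119905190),
  effect_allele = c("T", "A", "T"),
  other_allele = c("C", "G", "C"),
  eaf = c(0.38, 0.33, 0.32),
  beta_exposure = c(-0.147, -0.207, -0.136),
  se_exposure = c(0.01429, 0.01429, 0.01429),
  p_exposure = c(1.6e-21, 3.3e-38, 1.2e-17),
  beta_outcome = c(-0.029, 0.037, -0.037),
  se_outcome = c(0.026, 0.026, 0.027),
  p_outcome = c(0.2646856, 0.1547139, 0.17057),
  stringsAsFactors = FALSE
)

# harmonized_variants view of a combined table (pre-aligned, flipped = FALSE)
as_harmonized <- function(tab) {
  out <- data.frame(
    variant_id = tab$variant_id,
    effect_allele = tab$effect_allele, other_allele = tab$other_allele,
    beta_exposure = tab$beta_exposure, se_exposure = tab$se_exposure,
    p_exposure = tab$p_exposure,
    beta_outcome = tab$beta_outcome, se_outcome = tab$se_outcome,
    p_outcome = tab$p_outcome, flipped = FALSE, stringsAsFactors = FALSE
  )
  class(out) <- c("harmonized_variants", "data.frame")
  out
}

# single-trait variant_assoc view (side = "exposure" or "outcome")
as_assoc <- function(tab, side) {
  out <- data.frame(
    variant_id = tab$variant_id, chrom = tab$chrom, pos = tab$pos,
    effect_allele = tab$effect_allele, other_allele = tab$other_allele,
    eaf = tab$eaf,
    beta = tab[[paste0("beta_", side)]],
    se = tab[[paste0("se_", side)]],
    pvalue = tab[[paste0("p_", side)]],
    stringsAsFactors = FALSE
  )
  class(out) <- c("variant_assoc", "data.frame")
  out
}

# the four instruments retained for the T2DM analysis
t2dm_instruments <- function() as_harmonized(table1[table1$variant_id != "rs4420638", ])

# simple synthetic harmonized set: beta_outcome = alpha + theta * beta_exposure
make_harmonized <- function(bx, sy, theta = 0.1, alpha = 0, noise = 0,
                            sx = 0.01, ids = sprintf("rs%03d", seq_along(bx))) {
  out <- data.frame(
    variant_id = ids,
    effect_allele = "A", other_allele = "G",
    beta_exposure = bx, se_exposure = sx, p_exposure = 1e-12,
    beta_outcome = alpha + theta * bx + noise,
    se_outcome = sy, p_outcome = 0.5, flipped = FALSE,
    stringsAsFactors = FALSE
  )
  class(out) <- c("harmonized_variants", "data.frame")
  out
}

# brute-force weighted-mean oracle for ratio pooling
oracle_weighted_mean <- function(b, w) sum(w * b) / sum(w)
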