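# shared fixtures and independent oracles

make_samples_df <- function(ids, patch = "P1", lat = 53, lon = 19) {
  data.frame(individual_id = ids, patch_id = patch, lat = lat, lon = lon,
             stringsAsFactors = FALSE)
}

# small hand-written dataset: 3 individuals x 2 loci, two patches
make_tiny_dataset <- function() {
  ph <- matrix(c(1L, 0L,
                 0L, 1L,
                 1L, NA), nrow = 3, byrow = TRUE,
               dimnames = list(c("A01", "A02", "B01"), c("L1", "L2")))
  sm <- data.frame(individual_id = c("A01", "A02", "B01"),
                   patch_id = c("P1", "P1", "P2"),
                   lat = c(53.1, 53.1, 53.5), lon = c(19.0, 19.0, 19.4),
                   stringsAsFactors = FALSE)
  aflp_dataset(dominant_matrix(ph), sample_table(sm))
}

# a dataset with individuals but no loci (prior-recovery harness)
make_empty_locus_dataset <- function(n = 10) {
  ids <- sprintf("i%02d", seq_len(n))
  ph <- matrix(integer(0), nrow = n, ncol = 0, dimnames = list(ids, NULL))
  aflp_dataset(dominant_matrix(ph), sample_table(make_samples_df(ids)))
}

write_tiny_tsvs <- function(dir) {
  gpath <- file.path(dir, "geno.tsv")
  spath <- file.path(dir, "samples.tsv")
  writeLines(c("# tiny fixture",
               "individual_id\tL1\tL2",
               "A01\t1\t0",
               "A02\t0\t1",
               "B01\t1\t?"), gpath)
  writeLines(c("individual_id\tpatch_id\tlat\tlon",
               "A01\tP1\t53.1\t19.0",
               "A02\tP1\t53.1\t19.0",
               "B01\tP2\t53.5\t19.4"), spath)
  list(genotype = gpath, samples = spath)
}

# exact joint phenotype probabilities of a non-inbred pair from Jacquard
# condensed identity coefficients (d7 = both allele pairs IBD, d8 = one,
# d9 = none); band absence = null homozygote, null-allele frequency q
pair_phenotype_probs <- function(q, d7, d8, d9) {
  p00 <- d7 * q^2 + d8 * q^3 + d9 * q^4
  p0 <- q^2
  c(`00` = p00, `01` = p0 - p00, `10` = p0 - p00, `11` = 1 - 2 * p0 + p00)
}

# expectation of the per-locus kinship ratio under a relationship class,
# by full enumeration of the 4 phenotype-pair cells
expected_locus_kinship <- function(q, d7, d8, d9) {
  pr <- pair_phenotype_probs(q, d7, d8, d9)
  cells <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  comp <- locus_kinship(cells[, 1], cells[, 2], rep(q, 4))
  sum(pr * comp$numerator) / comp$weight[1]
}

# quadrature oracle for the posterior mean of sqrt(x) under Beta(a1, b1)
quad_mean_sqrt_beta <- function(a1, b1) {
  stats::integrate(function(x) sqrt(x) * stats::dbeta(x, a1, b1), 0, 1,
                   rel.tol = 1e-12, abs.tol = 1e-14)$value
}
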