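#' Construct a dominant-marker phenotype matrix
#'
#' AFLP and similar dominant markers are scored as band presence (1) or
#' absence (0) per individual and locus; band absence corresponds to the
#' homozygous null (recessive) genotype.  Missing scores are `NA` (written
#' as `?` on disk).
#'
#' @param phenotypes integer/numeric matrix, individuals x loci, values in
#'   `{0, 1, NA}`.
#' @param individual_ids,locus_ids optional identifier vectors; default to
#'   the matrix dimnames.
#' @return an integer matrix of class `dominant_matrix` with unique
#'   dimnames.
#' @export
dominant_matrix <- function(phenotypes, individual_ids = rownames(phenotypes),
                            locus_ids = colnames(phenotypes)) {
  .assert(is.matrix(phenotypes), "phenotypes must be a matrix", "aflpsgs_format_error")
  if (is.null(individual_ids)) {
    individual_ids <- sprintf("ind%d", seq_len(nrow(phenotypes)))
  }
  if (is.null(locus_ids)) locus_ids <- sprintf("L%d", seq_len(ncol(phenotypes)))
  individual_ids <- as.character(individual_ids)
  locus_ids <- as.character(locus_ids)
  .assert(length(individual_ids) == nrow(phenotypes) &&
          length(locus_ids) == ncol(phenotypes),
          "identifier lengths do not match matrix dimensions", "aflpsgs_format_error")
  .assert(!anyDuplicated(individual_ids),
          "duplicated individual_id", "aflpsgs_consistency_error")
  .assert(!anyDuplicated(locus_ids),
          "duplicated locus_id", "aflpsgs_consistency_error")
  vals <- phenotypes[!is.na(phenotypes)]
  .assert(all(vals %in% c(0, 1)),
          "phenotype values must be 0, 1 or NA", "aflpsgs_format_error")
  if (ncol(phenotypes) > 0 && nrow(phenotypes) > 0) {
    .assert(all(colSums(!is.na(phenotypes)) > 0),
            "every locus needs at least one non-missing score", "aflpsgs_format_error")
  }
  m <- matrix(as.integer(phenotypes), nrow = nrow(phenotypes),
              dimnames = list(individual_ids, locus_ids))
  class(m) <- c("dominant_matrix", class(m))
  m
}

#' Construct a sample table
#'
#' One row per individual: patch (sampling point, the field-study
#' "population") membership and WGS84 coordinates in decimal degrees.
#' All individuals of a patch must share identical coordinates, since a
#' patch is a single sampled point.
#'
#' @param df data frame with columns `individual_id`, `patch_id`, `lat`,
#'   `lon`.
#' @return validated data frame of class `sample_table`.
#' @export
sample_table <- function(df) {
  .assert(is.data.frame(df), "samples must be a data frame", "aflpsgs_format_error")
  need <- c("individual_id", "patch_id", "lat", "lon")
  .assert(all(need %in% names(df)),
          paste("sample table needs columns:", paste(need, collapse = ", ")),
          "aflpsgs_format_error")
  df <- df[, need]
  df$individual_id <- as.character(df$individual_id)
  df$patch_id <- as.character(df$patch_id)
  df$lat <- as.numeric(df$lat)
  df$lon <- as.numeric(df$lon)
  .assert(!anyDuplicated(df$individual_id),
          "duplicated individual_id in sample table", "aflpsgs_consistency_error")
  .assert(all(is.finite(df$lat)) && all(df$lat >= -90 & df$lat <= 90),
          "lat must lie in [-90, 90]", "aflpsgs_range_error")
  .assert(all(is.finite(df$lon)) && all(df$lon >= -180 & df$lon <= 180),
          "lon must lie in [-180, 180]", "aflpsgs_range_error")
  coords_per_patch <- tapply(paste(df$lat, df$lon), df$patch_id,
                             function(x) length(unique(x)))
  .assert(all(coords_per_patch == 1),
          "individuals sharing a patch_id must share identical coordinates",
          "aflpsgs_consistency_error")
  rownames(df) <- NULL
  class(df) <- c("sample_table", "data.frame")
  df
}

#' Bundle a phenotype matrix and sample table into a dataset
#'
#' @param matrix a [dominant_matrix()].
#' @param samples a [sample_table()]; rows are reordered to match the
#'   matrix rows.
#' @return list of class `aflp_dataset` with elements `phenotypes` and
#'   `samples`.
#' @export
aflp_dataset <- function(matrix, samples) {
  if (!inherits(matrix, "dominant_matrix")) matrix <- dominant_matrix(matrix)
  if (!inherits(samples, "sample_table")) samples <- sample_table(samples)
  ids <- rownames(matrix)
  .assert(setequal(ids, samples$individual_id),
          "individuals in genotype matrix and sample table differ",
          "aflpsgs_consistency_error")
  samples <- samples[match(ids, samples$individual_id), ]
  rownames(samples) <- NULL
  class(samples) <- c("sample_table", "data.frame")
  structure(list(phenotypes = matrix, samples = samples),
            class = "aflp_dataset")
}

#' @export
print.aflp_dataset <- function(x, ...) {
  cat("AFLP dominant-marker dataset\n")
  cat(sprintf("  %d individuals x %d loci, %d patches\n",
              nrow(x$phenotypes), ncol(x$phenotypes),
              length(unique(x$samples$patch_id))))
  miss <- mean(is.na(x$phenotypes))
  cat(sprintf("  missing scores: %.1f%%\n", 100 * if (is.nan(miss)) 0 else miss))
  invisible(x)
}

#' Number of individuals and loci
#' @param ds an `aflp_dataset`.
#' @return named integer vector.
#' @export
dim_dataset <- function(ds) {
  c(individuals = nrow(ds$phenotypes), loci = ncol(ds$phenotypes))
}

.read_tsv <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    check.names = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
}

#' Read a dataset from genotype and sample TSV files
#'
#' Genotype file: first column `individual_id`, one column per locus, cells
#' in `{0, 1, ?}` (`?` = missing).  Sample file: columns `individual_id`,
#' `patch_id`, `lat`, `lon`.  Both tab-delimited, UTF-8, `#` comment lines
#' ignored.
#'
#' @param genotype_path,sample_path file paths.
#' @return an [aflp_dataset()].
#' @export
read_dataset <- function(genotype_path, sample_path) {
  g <- .read_tsv(genotype_path)
  .assert(ncol(g) >= 2 && names(g)[1] == "individual_id",
          "genotype file must start with an individual_id column",
          "aflpsgs_format_error")
  ids <- g$individual_id
  .assert(!anyDuplicated(ids), "duplicated individual_id in genotype file",
          "aflpsgs_consistency_error")
  cells <- as.matrix(g[, -1, drop = FALSE])
  ok <- cells %in% c("0", "1", "?")
  .assert(all(ok), sprintf("unknown genotype symbol: %s",
                           paste(utils::head(unique(cells[!ok]), 3), collapse = ", ")),
          "aflpsgs_format_error")
  cells[cells == "?"] <- NA
  ph <- matrix(as.integer(cells), nrow = nrow(g),
               dimnames = list(ids, colnames(cells)))
  s <- .read_tsv(sample_path)
  aflp_dataset(dominant_matrix(ph), sample_table(s))
}

#' Write a dataset to genotype and sample TSV files
#'
#' Inverse of [read_dataset()]; `NA` scores are written as `?`.
#'
#' @param ds an `aflp_dataset`.
#' @param genotype_path,sample_path output file paths.
#' @return invisibly, the two paths.
#' @export
write_dataset <- function(ds, genotype_path, sample_path) {
  ph <- ds$phenotypes
  cells <- matrix(as.character(ph), nrow = nrow(ph))
  cells[is.na(cells)] <- "?"
  g <- data.frame(individual_id = rownames(ph), cells,
                  check.names = FALSE, stringsAsFactors = FALSE)
  names(g) <- c("individual_id", colnames(ph))
  utils::write.table(g, genotype_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  s <- as.data.frame(ds$samples)
  utils::write.table(s, sample_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(c(genotype_path, sample_path))
}

#' Filter loci by band-presence frequency
#'
#' Retains exactly the loci whose band-presence frequency f (among
#' non-missing scores) satisfies `lower < f < upper` (strict).  Loci close
#' to fixation carry little information for dominant markers and are prone
#' to scoring artefacts.
#'
#' @param ds an `aflp_dataset`.
#' @param lower,upper retention band, `0 <= lower < upper <= 1`;
#'   defaults 0.03 and 0.97.
#' @return filtered `aflp_dataset`; dropped locus ids in
#'   `attr(, "dropped_loci")`.
#' @export
filter_loci <- function(ds, lower = 0.03, upper = 0.97) {
  .assert(.is_prop(lower) && .is_prop(upper) && lower < upper,
          "need 0 <= lower < upper <= 1", "aflpsgs_range_error")
  f <- colMeans(ds$phenotypes == 1L, na.rm = TRUE)
  keep <- f > lower & f < upper
  if (!any(keep)) warning("all loci dropped by frequency filter; empty dataset")
  out <- aflp_dataset(
    dominant_matrix(unclass(ds$phenotypes)[, keep, drop = FALSE]),
    ds$samples)
  attr(out, "dropped_loci") <- colnames(ds$phenotypes)[!keep]
  out
}

#' Great-circle distance matrix between sampled individuals
#'
#' Haversine distances on a sphere of mean radius 6371.0088 km.  Individuals
#' sharing a patch have distance exactly 0.
#'
#' @param samples a [sample_table()] (or an `aflp_dataset`, whose sample
#'   table is used).
#' @return symmetric matrix of distances in km, dimnames = individual ids.
#' @export
geo_distance_matrix <- function(samples) {
  if (inherits(samples, "aflp_dataset")) samples <- samples$samples
  samples <- sample_table(as.data.frame(samples))
  pts <- cbind(samples$lon, samples$lat)
  n <- nrow(pts)
  D <- matrix(0, n, n, dimnames = list(samples$individual_id, samples$individual_id))
  for (k in seq_len(n)) {
    D[, k] <- geosphere::distHaversine(pts, pts[k, ], r = 6371008.8) / 1000
  }
  D <- (D + t(D)) / 2   # enforce exact symmetry against float asymmetries
  # same-patch pairs are the same point: force exact zeros
  same <- outer(samples$patch_id, samples$patch_id, "==")
  D[same] <- 0
  diag(D) <- 0
  D
}
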