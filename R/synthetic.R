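# Seeded generators producing dominant-marker datasets with known truth.
# Defaults mirror a patch-sampled study design over a ~300 km agricultural
# landscape: few individuals per patch, patches as single points.

# place patches in an extent_km x extent_km square and convert to WGS84
# around a reference point; distances are then (near-)planar km
.patch_coords <- function(n_patches, extent_km = 300, base_lat = 53.5,
                          base_lon = 19.5) {
  x <- stats::runif(n_patches, 0, extent_km)
  y <- stats::runif(n_patches, 0, extent_km)
  .km_to_lonlat(x, y, base_lat, base_lon)
}

.km_to_lonlat <- function(x_km, y_km, base_lat = 53.5, base_lon = 19.5) {
  km_per_deg <- pi * 6371.0088 / 180
  lat <- base_lat + y_km / km_per_deg
  lon <- base_lon + x_km / (km_per_deg * cos(base_lat * pi / 180))
  data.frame(lat = lat, lon = lon)
}

.make_samples <- function(ids, patch_of, coords) {
  sample_table(data.frame(individual_id = ids,
                          patch_id = patch_of,
                          lat = coords$lat[match(patch_of, rownames(coords))],
                          lon = coords$lon[match(patch_of, rownames(coords))],
                          stringsAsFactors = FALSE))
}

# dominant phenotypes from per-individual band-absence probabilities
.phenotypes_from_p0 <- function(P0, ids, loci) {
  ph <- matrix(1L - stats::rbinom(length(P0), 1, as.vector(P0)),
               nrow = nrow(P0), dimnames = list(ids, loci))
  dominant_matrix(ph)
}

#' Generate an unstructured (panmictic) dominant-marker dataset
#'
#' Null-allele frequencies drawn from a beta law; genotypes at
#' Hardy-Weinberg (band absence with probability q^2); individuals grouped
#' into patches placed uniformly at random in a square landscape.  The
#' null model for permutation and type-I-error checks.
#'
#' @param n individuals (>= 2).
#' @param L loci (>= 1).
#' @param q_dist beta shape parameters `c(a, b)` for the null-allele
#'   frequency; the default `c(1, 1)` is uniform.
#' @param seed optional integer seed.
#' @param n_patches number of patches (default about n/10, echoing
#'   patch-sampled field designs).
#' @param extent_km side of the square landscape.
#' @return list with `dataset` (an [aflp_dataset()]) and `truth` record.
#' @export
gen_unstructured <- function(n, L, q_dist = c(1, 1), seed = NULL,
                             n_patches = max(1, ceiling(n / 10)),
                             extent_km = 300) {
  .assert(n >= 2 && L >= 1, "need n >= 2 and L >= 1", "aflpsgs_range_error")
  .with_seed(seed, {
    q <- stats::rbeta(L, q_dist[1], q_dist[2])
    ids <- sprintf("ind%04d", seq_len(n))
    loci <- sprintf("L%03d", seq_len(L))
    P0 <- matrix(q^2, n, L, byrow = TRUE)
    mat <- .phenotypes_from_p0(P0, ids, loci)
    patch_of <- sprintf("P%02d", rep_len(seq_len(n_patches), n))
    coords <- .patch_coords(n_patches, extent_km)
    rownames(coords) <- sprintf("P%02d", seq_len(n_patches))
    ds <- aflp_dataset(mat, .make_samples(ids, patch_of, coords))
    truth <- list(generator = "gen_unstructured", seed = seed, q = q,
                  fst = 0, extent_km = extent_km, n_patches = n_patches)
    list(dataset = ds, truth = truth)
  })
}

#' Generate an island-model dataset with known FST
#'
#' Ancestral null-allele frequencies q ~ U(0.1, 0.9); per-deme frequencies
#' from the Balding-Nichols law Beta(q(1-FST)/FST, (1-q)(1-FST)/FST);
#' Hardy-Weinberg dominant phenotypes within demes.  Calibration oracle
#' for the FST estimator and the outlier scan.
#'
#' @param n_demes,n_per_deme,L design sizes.
#' @param target_fst differentiation parameter in (0, 1).
#' @param seed optional integer seed.
#' @param extent_km side of the square landscape demes are scattered over.
#' @return list with `dataset` and `truth` (ancestral and per-deme
#'   frequencies).
#' @export
gen_island <- function(n_demes, n_per_deme, L, target_fst, seed = NULL,
                       extent_km = 300) {
  .assert(target_fst > 0 && target_fst < 1, "target_fst must lie in (0, 1)",
          "aflpsgs_range_error")
  .with_seed(seed, {
    q_anc <- stats::runif(L, 0.1, 0.9)
    sh1 <- q_anc * (1 - target_fst) / target_fst
    sh2 <- (1 - q_anc) * (1 - target_fst) / target_fst
    Qd <- matrix(stats::rbeta(n_demes * L, rep(sh1, each = n_demes),
                              rep(sh2, each = n_demes)), n_demes, L)
    n <- n_demes * n_per_deme
    ids <- sprintf("ind%05d", seq_len(n))
    loci <- sprintf("L%03d", seq_len(L))
    deme_of <- rep(seq_len(n_demes), each = n_per_deme)
    P0 <- Qd[deme_of, , drop = FALSE]^2
    mat <- .phenotypes_from_p0(P0, ids, loci)
    coords <- .patch_coords(n_demes, extent_km)
    rownames(coords) <- sprintf("D%03d", seq_len(n_demes))
    ds <- aflp_dataset(mat, .make_samples(ids, sprintf("D%03d", deme_of), coords))
    truth <- list(generator = "gen_island", seed = seed, q_ancestral = q_anc,
                  q_deme = Qd, fst = target_fst)
    list(dataset = ds, truth = truth)
  })
}

#' Generate pairs of individuals with known relationship
#'
#' Founder genotypes are drawn from population frequencies and relatives
#' produced by Mendelian transmission; each pair occupies its own patch.
#' True kinship: unrelated 0, parent-offspring 0.25, full sibs 0.25,
#' self (clonal duplicate) 0.5.
#'
#' @param n_pairs number of pairs.
#' @param L loci.
#' @param relationship one of `"unrelated"`, `"parent_offspring"`,
#'   `"full_sib"`, `"self"`.
#' @param seed optional integer seed.
#' @param q_range uniform range for null-allele frequencies.
#' @return list with `dataset`, and `truth` carrying per-pair ids and the
#'   true kinship.
#' @export
gen_related_pairs <- function(n_pairs, L,
                              relationship = c("unrelated", "parent_offspring",
                                               "full_sib", "self"),
                              seed = NULL, q_range = c(0.1, 0.9)) {
  relationship <- match.arg(relationship)
  .assert(L >= 1 && n_pairs >= 1, "need n_pairs >= 1 and L >= 1",
          "aflpsgs_range_error")
  .with_seed(seed, {
    q <- stats::runif(L, q_range[1], q_range[2])
    # genotypes as null-allele copy number; one matrix per pair member
    draw_geno <- function() {
      matrix(stats::rbinom(n_pairs * L, 2, rep(q, each = n_pairs)), n_pairs, L)
    }
    pass_allele <- function(G) {
      # one allele sampled from a parental genotype (copy count 0..2)
      matrix(stats::rbinom(n_pairs * L, 1, as.vector(G) / 2), n_pairs, L)
    }
    pop_allele <- function() {
      matrix(stats::rbinom(n_pairs * L, 1, rep(q, each = n_pairs)), n_pairs, L)
    }
    if (relationship == "unrelated") {
      Ga <- draw_geno(); Gb <- draw_geno()
    } else if (relationship == "parent_offspring") {
      Ga <- draw_geno()
      Gb <- pass_allele(Ga) + pop_allele()
    } else if (relationship == "full_sib") {
      Gm <- draw_geno(); Gf <- draw_geno()
      Ga <- pass_allele(Gm) + pass_allele(Gf)
      Gb <- pass_allele(Gm) + pass_allele(Gf)
    } else {
      Ga <- draw_geno(); Gb <- Ga
    }
    truth_kinship <- c(unrelated = 0, parent_offspring = 0.25,
                       full_sib = 0.25, self = 0.5)[[relationship]]
    ids_a <- sprintf("p%05d_a", seq_len(n_pairs))
    ids_b <- sprintf("p%05d_b", seq_len(n_pairs))
    loci <- sprintf("L%03d", seq_len(L))
    ph <- rbind(1L * (Ga < 2), 1L * (Gb < 2))
    ord <- as.vector(rbind(seq_len(n_pairs), n_pairs + seq_len(n_pairs)))
    ph <- ph[ord, , drop = FALSE]
    ids <- as.vector(rbind(ids_a, ids_b))
    rownames(ph) <- ids; colnames(ph) <- loci
    patch_of <- rep(sprintf("pair%05d", seq_len(n_pairs)), each = 2)
    coords <- .patch_coords(n_pairs)
    rownames(coords) <- sprintf("pair%05d", seq_len(n_pairs))
    ds <- aflp_dataset(dominant_matrix(ph), .make_samples(ids, patch_of, coords))
    truth <- list(generator = "gen_related_pairs", seed = seed, q = q,
                  relationship = relationship,
                  pairs = data.frame(i = ids_a, j = ids_b,
                                     kinship = truth_kinship,
                                     stringsAsFactors = FALSE))
    list(dataset = ds, truth = truth)
  })
}

#' Generate a sample with beta-distributed individual inbreeding
#'
#' Fi ~ Beta with mean `f_mean` and concentration `f_shape` (shapes
#' `f_mean * f_shape` and `(1 - f_mean) * f_shape`); band absence with
#' probability q^2 + Fi q(1 - q).
#'
#' @param n individuals.
#' @param L loci.
#' @param f_mean mean inbreeding coefficient in \[0, 1); `f_mean = 0`
#'   degenerates to Hardy-Weinberg.
#' @param f_shape beta concentration (a + b).
#' @param seed optional integer seed.
#' @param q_range uniform range of null-allele frequencies.
#' @return list with `dataset` and `truth` (per-individual Fi, q).
#' @export
gen_inbred <- function(n, L, f_mean, f_shape = 5, seed = NULL,
                       q_range = c(0.1, 0.9)) {
  .assert(f_mean >= 0 && f_mean < 1, "f_mean must lie in [0, 1)",
          "aflpsgs_range_error")
  .with_seed(seed, {
    q <- stats::runif(L, q_range[1], q_range[2])
    Fi <- if (f_mean == 0) rep(0, n)
          else stats::rbeta(n, f_mean * f_shape, (1 - f_mean) * f_shape)
    P0 <- outer(Fi, q, function(f, qq) qq^2 + f * qq * (1 - qq))
    ids <- sprintf("ind%04d", seq_len(n))
    loci <- sprintf("L%03d", seq_len(L))
    mat <- .phenotypes_from_p0(P0, ids, loci)
    n_patches <- max(1, ceiling(n / 10))
    patch_of <- sprintf("P%02d", rep_len(seq_len(n_patches), n))
    coords <- .patch_coords(n_patches)
    rownames(coords) <- sprintf("P%02d", seq_len(n_patches))
    ds <- aflp_dataset(mat, .make_samples(ids, patch_of, coords))
    truth <- list(generator = "gen_inbred", seed = seed, q = q, Fi = Fi,
                  f_mean = f_mean, f_shape = f_shape)
    list(dataset = ds, truth = truth)
  })
}

# sampled demes at ~log-spaced lattice distances from a random anchor,
# so pair distances span adjacent demes up to the full landscape extent
.multiscale_demes <- function(grid, n_patches) {
  d <- grid * grid
  anchor_r <- sample.int(grid, 1)
  anchor_c <- sample.int(grid, 1)
  targets <- unique(round(exp(seq(0, log(sqrt(2) * (grid - 1)),
                                  length.out = n_patches - 1))))
  picked <- (anchor_r - 1) * grid + anchor_c
  all_r <- rep(seq_len(grid), each = grid)
  all_c <- rep(seq_len(grid), times = grid)
  all_idx <- (all_r - 1) * grid + all_c
  dist_to_anchor <- sqrt((all_r - anchor_r)^2 + (all_c - anchor_c)^2)
  k <- 1
  while (length(picked) < n_patches) {
    tgt <- targets[(k - 1) %% length(targets) + 1]
    cand <- setdiff(all_idx[order(abs(dist_to_anchor - tgt))], picked)
    pool <- utils::head(cand, 4)   # a little angular variety near the target ring
    picked <- c(picked, pool[sample.int(length(pool), 1)])
    k <- k + 1
  }
  sort(picked[seq_len(n_patches)])
}

# rook-neighbour random-walk transition matrix of a grid x grid lattice
.lattice_walk <- function(grid) {
  d <- grid * grid
  P <- matrix(0, d, d)
  idx <- function(r, c) (r - 1) * grid + c
  for (r in seq_len(grid)) for (c in seq_len(grid)) {
    nb <- rbind(c(r - 1, c), c(r + 1, c), c(r, c - 1), c(r, c + 1))
    nb <- nb[nb[, 1] >= 1 & nb[, 1] <= grid & nb[, 2] >= 1 & nb[, 2] <= grid, ,
             drop = FALSE]
    P[idx(r, c), idx(nb[, 1], nb[, 2])] <- 1 / nrow(nb)
  }
  P
}

#' Forward-time stepping-stone landscape with drift and migration
#'
#' Deme allele frequencies evolve on a square lattice by drift (binomial
#' resampling of 2N genes) and migration.  Dispersal follows a geometric
#' random-walk kernel: a gene's parental deme is reached by a
#' nearest-neighbour lattice walk of length K ~ Geometric(1 - m)
#' (P(K = 0) = 1 - m), giving migration matrix (1-m)(I - mP)^{-1}.  Small
#' m is classic stepping-stone migration and produces isolation by
#' distance; m = 1 is the walk's stationary distribution, i.e. full
#' mixing (panmixia).  Sampled patches are lattice demes mapped onto an
#' `extent_km` square.
#'
#' @param grid demes per lattice side.
#' @param N_deme diploid individuals per deme.
#' @param m migrant/walk parameter in \[0, 1\].
#' @param generations forward-time generations (>= 1).
#' @param L loci.
#' @param n_patches_sampled,n_per_patch sampling design.
#' @param patch_layout `"multiscale"` (default) picks sampled demes at
#'   roughly log-spaced lattice distances from a random anchor — the
#'   field design of isolation-by-distance studies, which need pairs from
#'   adjacent patches out to the full extent; `"random"` samples demes
#'   uniformly.
#' @param seed optional integer seed.
#' @param extent_km side of the square landscape.
#' @param store_history keep the full per-generation frequency history in
#'   the truth record (memory-heavy; default `FALSE` stores initial and
#'   final frequencies).
#' @return list with `dataset` and `truth` (deme frequencies, sampled
#'   demes, parameters).
#' @export
gen_ibd_landscape <- function(grid = 20, N_deme = 50, m = 0.01,
                              generations = 200, L = 100,
                              n_patches_sampled = 15, n_per_patch = 8,
                              patch_layout = c("multiscale", "random"),
                              seed = NULL, extent_km = 300,
                              store_history = FALSE) {
  patch_layout <- match.arg(patch_layout)
  .assert(m >= 0 && m <= 1, "m must lie in [0, 1]", "aflpsgs_range_error")
  .assert(.is_count(generations) && generations >= 1,
          "generations must be >= 1", "aflpsgs_range_error")
  d <- grid * grid
  .assert(n_patches_sampled <= d, "cannot sample more patches than demes",
          "aflpsgs_range_error")
  P <- .lattice_walk(grid)
  M <- if (m >= 1) {
    deg <- ifelse(P > 0, 1, 0)
    pi_st <- rowSums(deg) / sum(deg)
    matrix(pi_st, d, d, byrow = TRUE)
  } else if (m <= 0) {
    diag(d)
  } else {
    (1 - m) * solve(diag(d) - m * P)
  }
  .with_seed(seed, {
    q0 <- stats::runif(L, 0.1, 0.9)
    Q <- matrix(q0, d, L, byrow = TRUE)
    history <- if (store_history) vector("list", generations) else NULL
    for (g in seq_len(generations)) {
      Qm <- M %*% Q
      Q <- matrix(stats::rbinom(d * L, 2 * N_deme, as.vector(Qm)),
                  d, L) / (2 * N_deme)
      if (store_history) history[[g]] <- Q
    }
    sampled <- if (patch_layout == "random") {
      sort(sample.int(d, n_patches_sampled))
    } else {
      .multiscale_demes(grid, n_patches_sampled)
    }
    # lattice coordinates (cell centres) mapped onto the landscape square
    rr <- (sampled - 1) %/% grid + 1
    cc <- (sampled - 1) %% grid + 1
    step <- extent_km / grid
    coords <- .km_to_lonlat((cc - 0.5) * step, (rr - 0.5) * step)
    patch_ids <- sprintf("D%03d", sampled)
    rownames(coords) <- patch_ids
    n <- n_patches_sampled * n_per_patch
    ids <- sprintf("ind%05d", seq_len(n))
    loci <- sprintf("L%03d", seq_len(L))
    deme_of <- rep(seq_len(n_patches_sampled), each = n_per_patch)
    # sampled individuals are offspring of the post-migration parental
    # pool: at m = 1 this is the global pool (true panmixia)
    Qs <- M %*% Q
    P0 <- Qs[sampled[deme_of], , drop = FALSE]^2
    mat <- .phenotypes_from_p0(P0, ids, loci)
    ds <- aflp_dataset(mat, .make_samples(ids, patch_ids[deme_of], coords))
    truth <- list(generator = "gen_ibd_landscape", seed = seed,
                  grid = grid, N_deme = N_deme, m = m,
                  generations = generations, extent_km = extent_km,
                  q_initial = q0, q_final = Q, sampled_demes = sampled,
                  history = history)
    list(dataset = ds, truth = truth)
  })
}

#' Serialize a generator truth record to JSON
#'
#' @param truth a truth record from one of the generators.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
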