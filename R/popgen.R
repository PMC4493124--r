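#' Pairwise linkage disequilibrium r-squared of two marker columns
#'
#' Squared Pearson correlation of the two code vectors, which for fully
#' homozygous biallelic data equals the classical haplotype r-squared.
#' Pairs with a missing value in either column are dropped; a column left
#' monomorphic after dropping gives `NA` (and is excluded from any
#' averaging done by callers).
#'
#' @param col_a,col_b numeric vectors of codes in \{0, 2, NA\}.
#' @return r-squared in [0, 1], or NA.
#' @export
pairwise_r2 <- function(col_a, col_b) {
  keep <- !is.na(col_a) & !is.na(col_b)
  a <- col_a[keep]
  b <- col_b[keep]
  if (length(a) < 2 || length(unique(a)) < 2 || length(unique(b)) < 2) {
    return(NA_real_)
  }
  cor(a, b)^2
}

# per-chromosome r2 matrix; suppress sd-zero warnings, monomorphics give NA
r2_matrix <- function(codes) {
  suppressWarnings(cor(codes, use = "pairwise.complete.obs")^2)
}

#' Linkage-disequilibrium decay curve
#'
#' All intra-chromosomal marker pairs closer than `max_dist` bp are binned
#' into half-open physical-distance bins `[lower, upper)` of width `bin`
#' (100 kb by default) and the unweighted mean of the defined r-squared
#' values per bin is reported. Bins without any defined pair are emitted
#' with `mean_r2 = NA`.
#'
#' @param geno a `gs_geno`.
#' @param max_dist maximum pair distance in bp (default 10 Mb).
#' @param bin bin width in bp.
#' @return a tibble of class `gs_ld_curve` with columns `bin_lower`,
#'   `bin_upper`, `mean_r2`, `n_pairs`.
#' @export
ld_decay_curve <- function(geno, max_dist = 1e7, bin = 1e5) {
  stopifnot(inherits(geno, "gs_geno"))
  if (bin <= 0) abort("bin width must be > 0")
  pieces <- purrr::map(chrom_index_list(geno$map), function(idx) {
    if (length(idx) < 2) return(NULL)
    bp <- geno$map$bp[idx]
    r2 <- r2_matrix(geno$codes[, idx, drop = FALSE])
    ut <- upper.tri(r2)
    dist <- abs(outer(bp, bp, "-"))[ut]
    keep <- dist < max_dist
    tibble(dist = dist[keep], r2 = r2[ut][keep])
  })
  pairs <- dplyr::bind_rows(pieces)
  n_bins <- if (nrow(pairs) == 0) 0 else floor(max(pairs$dist) / bin) + 1
  if (n_bins == 0) {
    out <- tibble(bin_lower = double(), bin_upper = double(),
                  mean_r2 = double(), n_pairs = integer())
  } else {
    bin_width <- bin
    pairs$bin <- floor(pairs$dist / bin_width)
    agg <- pairs |>
      dplyr::filter(!is.na(.data$r2)) |>
      dplyr::group_by(.data$bin) |>
      dplyr::summarise(mean_r2 = mean(.data$r2), n_pairs = dplyr::n(),
                       .groups = "drop")
    out <- tibble(bin = 0:(n_bins - 1)) |>
      dplyr::left_join(agg, by = "bin") |>
      dplyr::mutate(
        bin_lower = .data$bin * bin_width,
        bin_upper = (.data$bin + 1) * bin_width,
        n_pairs = dplyr::coalesce(.data$n_pairs, 0L)
      ) |>
      dplyr::select("bin_lower", "bin_upper", "mean_r2", "n_pairs")
  }
  class(out) <- c("gs_ld_curve", class(out))
  out
}

#' Average LD between adjacent markers (ALAM)
#'
#' Mean of the defined r-squared values over all intra-chromosomal adjacent
#' marker pairs of a marker set (literal adjacent pairs of the subset, in
#' map order).
#'
#' @param geno a `gs_geno`.
#' @param markers optional marker-id subset (default: the full panel).
#' @return mean adjacent r-squared.
#' @export
alam <- function(geno, markers = NULL) {
  g <- if (is.null(markers)) geno else subset_geno(geno, markers = markers)
  vals <- purrr::map(chrom_index_list(g$map), function(idx) {
    if (length(idx) < 2) return(numeric(0))
    purrr::map_dbl(seq_len(length(idx) - 1), function(j) {
      pairwise_r2(g$codes[, idx[j]], g$codes[, idx[j + 1]])
    })
  })
  vals <- unlist(vals)
  if (length(vals) == 0) abort("marker subset has < 2 markers on every chromosome")
  mean(vals, na.rm = TRUE)
}

#' Realized kinship matrix (proportion IBS)
#'
#' Allele-sharing similarity for a fully homozygous panel:
#' `K[i, j]` is the fraction of markers at which lines i and j carry the
#' same genotype. The diagonal is 1; complementary lines score 0.
#'
#' @param geno a complete `gs_geno` (impute first).
#' @return an N x N matrix of class `gs_kinship` with line-id dimnames and
#'   attribute `mean_off_diagonal`.
#' @export
kinship_matrix <- function(geno) {
  stopifnot(inherits(geno, "gs_geno"))
  if (ncol(geno$codes) == 0) abort("zero markers")
  if (anyNA(geno$codes)) abort("genotypes must be complete; impute first")
  z <- geno$codes - 1  # codes 0/2 -> -1/+1; equal genotypes <=> product +1
  k <- (1 + tcrossprod(z) / ncol(z)) / 2
  dimnames(k) <- list(rownames(geno$codes), rownames(geno$codes))
  attr(k, "mean_off_diagonal") <- mean(k[upper.tri(k)])
  class(k) <- c("gs_kinship", class(k))
  k
}

#' Mean off-diagonal kinship
#' @param k a `gs_kinship`.
#' @return scalar mean of all pairwise (off-diagonal) similarities.
#' @export
mean_kinship <- function(k) {
  attr(k, "mean_off_diagonal") %||% mean(k[upper.tri(k)])
}

#' @describeIn kinship_matrix long-format view (line_1, line_2, kinship).
#' @param x a `gs_kinship`.
#' @param ... unused.
#' @export
tidy.gs_kinship <- function(x, ...) {
  ids <- rownames(x)
  ut <- which(upper.tri(x, diag = TRUE), arr.ind = TRUE)
  tibble(line_1 = ids[ut[, 1]], line_2 = ids[ut[, 2]],
         kinship = x[ut])
}

#' Estimate the realized (expanded) genetic map from line genotypes
#'
#' Adjacent-marker recombination fractions are estimated from the
#' discordance rate between neighbouring columns (the fraction of lines
#' whose genotypes differ), optionally back-transformed with the RIL
#' correction `c = R / (2 - 2R)`, and converted to map distance with the
#' inverse Haldane function `d = -50 * ln(1 - 2c)` cM. Distances accumulate
#' from 0 within each chromosome. Intervals whose estimated recombination
#' fraction reaches 0.5 are capped at `cap_cM` and flagged.
#'
#' Applied to lines derived after intermating, the resulting map is the
#' population's expanded map: accumulated recombination makes it longer
#' than the base F2 map, and more so the more intermating generations.
#'
#' @param geno a complete homozygous `gs_geno` with at least 30 lines.
#' @param cap_cM distance assigned to saturated intervals.
#' @param ril_correction apply the RIL back-transform (off by default:
#'   expanded maps are meant to absorb design effects).
#' @return a `gs_map` with re-estimated cM (bp and order unchanged);
#'   attribute `capped_intervals` counts saturated intervals.
#' @export
estimate_expanded_map <- function(geno, cap_cM = 200, ril_correction = FALSE) {
  stopifnot(inherits(geno, "gs_geno"))
  if (nrow(geno$codes) < 30) {
    warn("fewer than 30 lines; expanded-map estimates will be noisy")
  }
  if (anyNA(geno$codes)) abort("genotypes must be complete; impute first")
  map <- geno$map
  new_cM <- numeric(nrow(map))
  capped <- 0L
  for (idx in chrom_index_list(map)) {
    if (length(idx) == 1) {
      new_cM[idx] <- 0
      next
    }
    x <- geno$codes[, idx, drop = FALSE]
    disc <- colMeans(x[, -1, drop = FALSE] != x[, -length(idx), drop = FALSE])
    cc <- if (ril_correction) disc / (2 - 2 * disc) else disc
    d <- numeric(length(cc))
    sat <- cc >= 0.5
    d[!sat] <- -50 * log(1 - 2 * cc[!sat])
    d[sat] <- cap_cM
    capped <- capped + sum(sat)
    new_cM[idx] <- cumsum(c(0, d))
  }
  out <- map
  out$cM <- new_cM
  # a zero-length estimate is a legitimate outcome, not a malformed map
  out <- suppressWarnings(genetic_map(out))
  attr(out, "capped_intervals") <- capped
  out
}
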