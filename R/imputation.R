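#' HMM parameters for missing-genotype imputation
#'
#' Two hidden states (AA, BB) for a fully inbred biparental panel.
#' Transition probability between adjacent markers d Morgans apart is the
#' Haldane recombination fraction (1 - exp(-2d)) / 2; emissions allow a
#' symmetric genotyping-error rate.
#'
#' @param error_rate genotyping error probability, in [0, 0.5).
#' @return a `gs_hmm_params` list.
#' @export
hmm_params <- function(error_rate = 0.01) {
  if (error_rate < 0 || error_rate >= 0.5) {
    abort("error_rate must be in [0, 0.5)")
  }
  structure(list(error_rate = error_rate, map_function = "haldane",
                 states = c("AA", "BB")), class = "gs_hmm_params")
}

haldane_c <- function(d_morgan) (1 - exp(-2 * d_morgan)) / 2

# forward-backward for one chromosome, vectorised over lines.
# obs: n_lines x n_mark matrix of codes 0/2/NA; d: Morgans between adjacent
# markers. Returns list(p_aa = posterior P(AA) matrix).
fb_chromosome <- function(obs, d, eps) {
  n <- nrow(obs)
  m <- ncol(obs)
  # emission likelihoods per state
  e_aa <- matrix(1, n, m)
  e_bb <- matrix(1, n, m)
  is0 <- !is.na(obs) & obs == 0
  is2 <- !is.na(obs) & obs == 2
  e_aa[is0] <- 1 - eps; e_aa[is2] <- eps
  e_bb[is2] <- 1 - eps; e_bb[is0] <- eps

  cvec <- haldane_c(d)
  a_aa <- matrix(0, n, m)  # scaled forward, P(state = AA)
  a_bb <- matrix(0, n, m)
  f1 <- 0.5 * e_aa[, 1]; f2 <- 0.5 * e_bb[, 1]
  s <- f1 + f2
  a_aa[, 1] <- f1 / s; a_bb[, 1] <- f2 / s
  for (j in seq_len(m - 1)) {
    cc <- cvec[j]
    f1 <- (a_aa[, j] * (1 - cc) + a_bb[, j] * cc) * e_aa[, j + 1]
    f2 <- (a_aa[, j] * cc + a_bb[, j] * (1 - cc)) * e_bb[, j + 1]
    s <- f1 + f2
    a_aa[, j + 1] <- f1 / s; a_bb[, j + 1] <- f2 / s
  }
  b_aa <- matrix(1, n, m)
  b_bb <- matrix(1, n, m)
  for (j in rev(seq_len(m - 1))) {
    cc <- cvec[j]
    t1 <- e_aa[, j + 1] * b_aa[, j + 1]
    t2 <- e_bb[, j + 1] * b_bb[, j + 1]
    g1 <- (1 - cc) * t1 + cc * t2
    g2 <- cc * t1 + (1 - cc) * t2
    s <- g1 + g2
    b_aa[, j] <- g1 / s * 2; b_bb[, j] <- g2 / s * 2  # rescale, arbitrary
  }
  num_aa <- a_aa * b_aa
  num_bb <- a_bb * b_bb
  num_aa / (num_aa + num_bb)
}

#' Impute missing genotypes with a two-state HMM
#'
#' Runs a forward-backward pass per line and chromosome over hidden states
#' \{AA, BB\}, with Haldane transition probabilities from the panel's own
#' genetic map and a symmetric emission error rate. Each missing cell is
#' replaced by the code of the posterior-mode state; observed cells are
#' never altered. A cell whose posterior is exactly 0.5 stays missing and
#' is reported in a message.
#'
#' @param geno a `gs_geno` (codes 0/2/NA).
#' @param params a `gs_hmm_params` (or a bare error rate).
#' @param return_posterior if TRUE, the returned object carries an
#'   attribute `posterior`: a matrix of P(AA) per cell.
#' @return an imputed `gs_geno`.
#' @export
impute_missing_hmm <- function(geno, params = hmm_params(),
                               return_posterior = FALSE) {
  stopifnot(inherits(geno, "gs_geno"))
  if (is.numeric(params)) params <- hmm_params(params)
  eps <- params$error_rate
  codes <- geno$codes
  post <- matrix(NA_real_, nrow(codes), ncol(codes), dimnames = dimnames(codes))
  out <- codes
  ties <- 0L
  for (idx in chrom_index_list(geno$map)) {
    if (length(idx) == 0) abort("chromosome with 0 markers")
    obs <- codes[, idx, drop = FALSE]
    if (length(idx) == 1) {
      # single marker: posterior = emission under the uniform prior
      p_aa <- matrix(ifelse(is.na(obs), 0.5, ifelse(obs == 0, 1 - eps, eps)),
                     nrow(obs), 1)
    } else {
      d <- diff(geno$map$cM[idx]) / 100
      p_aa <- fb_chromosome(obs, d, eps)
    }
    post[, idx] <- p_aa
    fill <- is.na(obs)
    if (any(fill)) {
      imp <- ifelse(p_aa[fill] > 0.5, 0, 2)
      tie <- p_aa[fill] == 0.5
      imp[tie] <- NA_real_
      ties <- ties + sum(tie)
      block <- out[, idx, drop = FALSE]
      block[fill] <- imp
      out[, idx] <- block
    }
  }
  if (ties > 0) {
    inform(paste0(ties, " cell(s) had posterior exactly 0.5 and were left missing"))
  }
  res <- genotypes(out, geno$map, rownames(out))
  if (return_posterior) attr(res, "posterior") <- post
  res
}

#' Impute a dense marker panel onto a sparsely genotyped population
#'
#' For every marker of the dense map and every line: if the dense marker
#' coincides with a sparse-panel marker (same chromosome and bp), its code
#' is copied; otherwise the two physically flanking sparse markers are
#' found — if they agree the shared genotype is assigned, if they disagree
#' the genotype of the physically nearer flank is taken, and at exactly
#' equidistant disagreeing flanks the cell is left missing. Beyond the
#' first/last sparse marker of a chromosome the single available flank is
#' used.
#'
#' @param sparse a complete `gs_geno` (run [impute_missing_hmm()] first).
#' @param dense_map a `gs_map` on the same physical coordinate system.
#' @return a `gs_geno` on `dense_map` for the sparse panel's lines.
#' @export
impute_cross_panel <- function(sparse, dense_map) {
  stopifnot(inherits(sparse, "gs_geno"), inherits(dense_map, "gs_map"))
  if (anyNA(sparse$codes)) {
    abort("sparse panel has missing codes; run impute_missing_hmm() first")
  }
  miss_chr <- setdiff(unique(dense_map$chrom), unique(sparse$map$chrom))
  if (length(miss_chr) > 0) {
    abort(paste0("dense map chromosome(s) absent from sparse panel: ",
                 paste(miss_chr, collapse = ", ")))
  }
  n <- nrow(sparse$codes)
  out <- matrix(NA_real_, n, nrow(dense_map),
                dimnames = list(rownames(sparse$codes), dense_map$marker))
  for (ch in unique(dense_map$chrom)) {
    didx <- which(dense_map$chrom == ch)
    sidx <- which(sparse$map$chrom == ch)
    sb <- sparse$map$bp[sidx]
    scodes <- sparse$codes[, sidx, drop = FALSE]
    for (jj in seq_along(didx)) {
      b <- dense_map$bp[didx[jj]]
      pos <- findInterval(b, sb)
      exact <- pos >= 1 && sb[pos] == b
      if (exact) {
        out[, didx[jj]] <- scodes[, pos]
      } else if (pos == 0) {
        out[, didx[jj]] <- scodes[, 1]
      } else if (pos == length(sb)) {
        out[, didx[jj]] <- scodes[, pos]
      } else {
        dl <- b - sb[pos]
        dr <- sb[pos + 1] - b
        left <- scodes[, pos]
        right <- scodes[, pos + 1]
        col <- if (dl < dr) left else if (dr < dl) right else {
          ifelse(left == right, left, NA_real_)
        }
        col[left == right] <- left[left == right]
        out[, didx[jj]] <- col
      }
    }
  }
  genotypes(out, dense_map, rownames(sparse$codes))
}
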