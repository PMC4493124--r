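#' Construct and validate a genetic map
#'
#' A genetic map is a tibble with one row per marker and columns `marker`
#' (unique id), `chrom` (integer chromosome), `cM` (genetic position,
#' centiMorgan) and `bp` (physical position, 1-based base pairs). Rows are
#' sorted into canonical (chrom, cM) order; within each chromosome the
#' genetic and physical orders must agree (both nondecreasing).
#'
#' @param df data frame with columns `marker`, `chrom`, `cM`, `bp`.
#' @return A validated map tibble of class `gs_map`, sorted by (chrom, cM).
#' @examples
#' genetic_map(data.frame(marker = c("m1", "m2", "m3"), chrom = 1,
#'                        cM = c(0, 10, 20), bp = c(1e5, 2e5, 3e5)))
#' @export
genetic_map <- function(df) {
  required <- c("marker", "chrom", "cM", "bp")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("map is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  map <- as_tibble(df)[required]
  map$marker <- as.character(map$marker)
  map$chrom <- as.integer(map$chrom)
  map$cM <- as.double(map$cM)
  map$bp <- as.double(map$bp)

  if (anyNA(map)) abort("map contains missing values")
  if (anyDuplicated(map$marker)) {
    dup <- map$marker[duplicated(map$marker)][1]
    abort(paste0("duplicate marker id: '", dup, "'"))
  }
  bad <- which(map$cM < 0 | map$bp < 1)[1]
  if (!is.na(bad)) {
    abort(paste0("negative or out-of-range coordinate at row ", bad,
                 " (marker '", map$marker[bad], "')"))
  }

  map <- dplyr::arrange(map, .data$chrom, .data$cM, .data$bp)
  # after sorting on cM, physical order must agree within chromosome
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    bp <- map$bp[idx]
    viol <- which(diff(bp) < 0)[1]
    if (!is.na(viol)) {
      abort(paste0("genetic and physical order disagree on chromosome ", ch,
                   " at row ", idx[viol + 1],
                   " (marker '", map$marker[idx[viol + 1]], "')"))
    }
  }
  if (map_length(map) <= 0 && nrow(map) > 1) {
    warn("map has zero total genetic length")
  }
  class(map) <- c("gs_map", class(tibble()))
  map
}

#' Read a genetic map from a delimited file
#'
#' Expects a header and columns `marker,chrom,cM,bp` (TSV or CSV, detected
#' from the delimiter in the header line). Rows failing the map invariants
#' (duplicate ids, negative coordinates, non-monotone order within a
#' chromosome) are rejected with the offending row named.
#'
#' @param path file path.
#' @return a `gs_map` tibble (see [genetic_map()]).
#' @export
read_map <- function(path) {
  header <- readLines(path, n = 1)
  delim <- if (grepl("\t", header)) "\t" else ","
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  genetic_map(df)
}

#' Write a genetic map
#' @param map a `gs_map`.
#' @param path output path; `.tsv` extension selects tab, otherwise comma.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  stopifnot(inherits(map, "gs_map"))
  delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  readr::write_delim(as_tibble(map), path, delim = delim)
  invisible(path)
}

#' Total genetic map length
#'
#' Sum over chromosomes of (max cM - min cM).
#' @param map a `gs_map`.
#' @return length in cM.
#' @export
map_length <- function(map) {
  spans <- tapply(map$cM, map$chrom, function(x) max(x) - min(x))
  sum(spans)
}

#' Average adjacent genetic distance of a marker set
#'
#' Defined as total map length divided by the number of markers in the set
#' (not by the number of intervals), the convention under which a
#' 6,240-cM map thinned to 800 markers has average spacing 7.80 cM.
#'
#' @param map a `gs_map` (the full map supplying the total length).
#' @param n_m marker-set size.
#' @return average spacing in cM.
#' @export
avg_adjacent_distance <- function(map, n_m) {
  stopifnot(n_m >= 1)
  map_length(map) / n_m
}

#' Synthetic base genome map
#'
#' Builds a maize-like base (F2-scale) map: `n_chr` chromosomes of equal
#' genetic length `total_cM / n_chr` and physical length `total_bp / n_chr`,
#' markers near-uniformly spaced with proportional cM and bp coordinates.
#' Defaults give a 1,800 cM / 2 Gb genome on 10 chromosomes.
#'
#' Marker positions are jittered around the uniform grid with a
#' deterministic low-discrepancy (golden-ratio) sequence: real marker
#' panels are never exactly equidistant, and a perfectly regular grid
#' creates degenerate exact-midpoint ties for flanking-marker imputation.
#' The first and last marker of each chromosome stay at the chromosome
#' ends, so total lengths are exact.
#'
#' @param n_markers total number of markers (distributed as evenly as
#'   possible over chromosomes).
#' @param n_chr number of chromosomes.
#' @param total_cM total genetic length (cM) of the base map.
#' @param total_bp total physical length (bp).
#' @param jitter fraction of the inter-marker spacing used for the
#'   deterministic position jitter (0 gives an exactly uniform grid).
#' @param prefix marker id prefix.
#' @return a `gs_map`.
#' @export
base_genome_map <- function(n_markers, n_chr = 10, total_cM = 1800,
                            total_bp = 2e9, jitter = 0.35, prefix = "m") {
  stopifnot(n_markers >= n_chr, jitter >= 0, jitter < 1)
  per_chr <- rep(n_markers %/% n_chr, n_chr)
  extra <- n_markers %% n_chr
  if (extra > 0) per_chr[seq_len(extra)] <- per_chr[seq_len(extra)] + 1
  chr_cM <- total_cM / n_chr
  chr_bp <- total_bp / n_chr
  phi <- (sqrt(5) - 1) / 2
  rows <- purrr::map(seq_len(n_chr), function(ch) {
    k <- per_chr[ch]
    frac <- (seq_len(k) - 1) / max(k - 1, 1)
    if (k > 2 && jitter > 0) {
      u <- ((seq_len(k) + (ch - 1) * k) * phi) %% 1  # low-discrepancy in [0,1)
      off <- (u - 0.5) * jitter / max(k - 1, 1)
      off[c(1, k)] <- 0  # chromosome ends stay put
      frac <- frac + off
    }
    tibble(
      marker = sprintf("%s%d_%d", prefix, ch, seq_len(k)),
      chrom = ch,
      cM = frac * chr_cM,
      bp = round(1 + frac * (chr_bp - 1))
    )
  })
  genetic_map(dplyr::bind_rows(rows))
}
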