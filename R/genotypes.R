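#' Genotype matrix container
#'
#' Bundles an N-line by M-marker matrix of allele-count codes with its
#' genetic map. Codes are 0 (AA, first parent), 2 (BB, second parent) or
#' `NA` (missing); the panel is assumed fully inbred, so no heterozygote
#' class exists. Columns are always in map order.
#'
#' @param codes numeric matrix, lines x markers, values in \{0, 2, NA\}.
#' @param map a `gs_map` with one row per column of `codes`.
#' @param line_ids optional character vector of line ids (default taken
#'   from `rownames(codes)` or generated as `L1..LN`).
#' @return an object of class `gs_geno`: a list with elements `codes`
#'   (matrix with line/marker dimnames) and `map`.
#' @export
genotypes <- function(codes, map, line_ids = NULL) {
  stopifnot(is.matrix(codes), inherits(map, "gs_map"))
  if (ncol(codes) != nrow(map)) {
    abort(paste0("codes has ", ncol(codes), " columns but map has ",
                 nrow(map), " markers"))
  }
  line_ids <- line_ids %||% rownames(codes) %||% paste0("L", seq_len(nrow(codes)))
  line_ids <- as.character(line_ids)
  if (anyDuplicated(line_ids)) abort("line ids must be unique")
  if (length(line_ids) != nrow(codes)) abort("line_ids length != number of rows")
  storage.mode(codes) <- "double"
  ok <- is.na(codes) | codes == 0 | codes == 2
  if (!all(ok)) {
    bad <- which(!ok)[1]
    abort(paste0("invalid genotype code ", codes[bad], " (allowed: 0, 2, NA)"))
  }
  dimnames(codes) <- list(line_ids, map$marker)
  structure(list(codes = codes, map = map), class = "gs_geno")
}

#' @export
print.gs_geno <- function(x, ...) {
  cat("<gs_geno> ", nrow(x$codes), " lines x ", ncol(x$codes), " markers, ",
      length(unique(x$map$chrom)), " chromosomes, ",
      round(map_length(x$map), 1), " cM; missing: ",
      sum(is.na(x$codes)), " cells\n", sep = "")
  invisible(x)
}

#' @export
dim.gs_geno <- function(x) dim(x$codes)

#' Line ids of a genotype panel
#' @param geno a `gs_geno`.
#' @return character vector.
#' @export
line_ids <- function(geno) rownames(geno$codes)

#' Subset a genotype panel
#'
#' @param geno a `gs_geno`.
#' @param lines line ids or indices to keep (default all).
#' @param markers marker ids to keep, in map order (default all).
#' @return a `gs_geno`.
#' @export
subset_geno <- function(geno, lines = NULL, markers = NULL) {
  codes <- geno$codes
  map <- geno$map
  if (!is.null(markers)) {
    unknown <- setdiff(markers, map$marker)
    if (length(unknown) > 0) {
      abort(paste0("unknown marker id(s): ", paste(head(unknown, 5), collapse = ", ")))
    }
    keep <- map$marker %in% markers
    map <- map[keep, ]
    class(map) <- c("gs_map", class(tibble()))
    codes <- codes[, keep, drop = FALSE]
  }
  if (!is.null(lines)) {
    codes <- codes[lines, , drop = FALSE]
  }
  genotypes(codes, map, rownames(codes))
}

#' Stack two genotype panels sharing a marker panel
#' @param a,b `gs_geno` objects with identical maps; line ids must not clash.
#' @return combined `gs_geno`.
#' @export
bind_geno <- function(a, b) {
  if (!identical(a$map$marker, b$map$marker)) {
    abort("panels have different marker sets; impute onto a common panel first")
  }
  genotypes(rbind(a$codes, b$codes), a$map)
}

#' @describeIn genotypes long-format view: one row per (line, marker) cell
#'   with columns line, marker, chrom, cM, bp, code.
#' @param x a `gs_geno`.
#' @param ... unused.
#' @export
tidy.gs_geno <- function(x, ...) {
  tibble(
    line = rep(rownames(x$codes), times = ncol(x$codes)),
    marker = rep(colnames(x$codes), each = nrow(x$codes)),
    code = as.vector(x$codes)
  ) |>
    dplyr::left_join(as_tibble(x$map), by = "marker")
}

default_dialect <- function() c(A = 0, B = 2, `NA` = NA_real_)

#' Read a genotype matrix
#'
#' Reads a CSV whose first column holds line ids and remaining columns hold
#' per-marker genotype symbols. The column set must match the map's markers
#' exactly; columns are re-ordered to map order. The default symbol dialect
#' maps `A` to 0, `B` to 2 and `NA`/empty to missing; a heterozygote symbol
#' is rejected unless a dialect maps it (e.g. `c(A = 0, B = 2, H = NA)` to
#' discard residual heterozygous calls from pre-inbreeding intermediates).
#'
#' @param path CSV file path.
#' @param map a `gs_map` the panel must align to.
#' @param dialect named numeric vector mapping symbols to codes (values must
#'   be 0, 2 or NA).
#' @return a `gs_geno` with columns in map order.
#' @export
read_genotypes <- function(path, map, dialect = default_dialect()) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE, na = character())
  ids <- df[[1]]
  sym <- as.matrix(df[, -1, drop = FALSE])
  extra <- setdiff(colnames(sym), map$marker)
  miss <- setdiff(map$marker, colnames(sym))
  if (length(extra) > 0 || length(miss) > 0) {
    abort(paste0("genotype columns do not match map: ",
                 if (length(miss) > 0) paste0("missing [", paste(head(miss, 5), collapse = ", "), "] "),
                 if (length(extra) > 0) paste0("unexpected [", paste(head(extra, 5), collapse = ", "), "]")))
  }
  sym <- sym[, map$marker, drop = FALSE]
  sym[sym == ""] <- "NA"
  known <- names(dialect)
  bad <- setdiff(unique(as.vector(sym)), known)
  if (length(bad) > 0) {
    abort(paste0("unknown genotype symbol '", bad[1], "'"))
  }
  codes <- matrix(dialect[as.vector(sym)], nrow = nrow(sym))
  genotypes(codes, map, ids)
}

#' Write a genotype matrix
#'
#' Inverse of [read_genotypes()]: codes 0/2/NA become symbols under the
#' dialect (default A/B/NA).
#'
#' @inheritParams read_genotypes
#' @param geno a `gs_geno`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(geno, path, dialect = default_dialect()) {
  stopifnot(inherits(geno, "gs_geno"))
  inv <- setNames(names(dialect), as.character(dialect))
  key <- as.character(geno$codes)
  key[is.na(geno$codes)] <- "NA"
  sym <- matrix(inv[key], nrow = nrow(geno$codes),
                dimnames = dimnames(geno$codes))
  df <- dplyr::bind_cols(tibble(line = rownames(sym)), as_tibble(sym))
  readr::write_csv(df, path)
  invisible(path)
}

#' Read plot-level phenotypes
#'
#' CSV with columns `line,replicate,value`: one row per plot.
#'
#' @param path CSV file path.
#' @return tibble with columns line (character), replicate (character),
#'   value (double); attribute `balanced` flags equal replication.
#' @export
read_phenotypes <- function(path) {
  df <- readr::read_csv(path, col_types = "ccd", progress = FALSE)
  missing_cols <- setdiff(c("line", "replicate", "value"), names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("phenotype file missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  reps <- table(df$line)
  attr(df, "balanced") <- length(unique(as.integer(reps))) == 1
  df
}

#' Per-line phenotype means
#' @param plots tibble of plot phenotypes (columns line, value).
#' @return tibble with columns line, mean_value, n_plots.
#' @export
line_means <- function(plots) {
  plots |>
    dplyr::group_by(.data$line) |>
    dplyr::summarise(mean_value = mean(.data$value), n_plots = dplyr::n(),
                     .groups = "drop")
}

#' Write a tabular result to CSV
#'
#' Dispatches on the result type: accuracy tables are written with the
#' canonical header `scenario,N_P,N_M,repeat,r_MP,r_MG`; kinship matrices as
#' a square CSV with line ids as both row labels (first column) and column
#' names; any other data frame is written as-is with its column order.
#' Numeric values are written at full precision so read-back reproduces
#' them to 1e-12.
#'
#' @param obj a tabular result (data frame, `gs_accuracy` or `gs_kinship`).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_table <- function(obj, path) {
  UseMethod("write_table")
}

#' @export
write_table.gs_kinship <- function(obj, path) {
  df <- dplyr::bind_cols(tibble(line = rownames(obj)),
                         as_tibble(unclass(obj), .name_repair = "minimal"))
  readr::write_csv(df, path)
  invisible(path)
}

#' @export
write_table.gs_accuracy <- function(obj, path) {
  out <- tibble(
    scenario = obj$scenario, N_P = obj$n_p, N_M = obj$n_m,
    "repeat" = obj$rep, r_MP = obj$r_mp, r_MG = obj$r_mg
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' @export
write_table.data.frame <- function(obj, path) {
  readr::write_csv(as_tibble(obj), path)
  invisible(path)
}
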