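#' SNP quality control
#'
#' Filters a lines-by-SNPs marker matrix (codes 0/1/2, `NA` = missing) by the
#' four standard genotyping-by-sequencing rules: missing-data rate, minor
#' allele frequency, heterozygosity rate, and homozygosity rate. A SNP is kept
#' only when it satisfies all four rules simultaneously. MAF, heterozygosity
#' and homozygosity rates are computed over non-missing calls; the missing
#' rate is computed over all lines.
#'
#' @param m numeric matrix, lines x SNPs, entries in \{0, 1, 2, NA\}; row and
#'   column names carry line and SNP identifiers.
#' @param max_missing maximum tolerated missing-call proportion per SNP
#'   (a SNP with missing rate >= `max_missing` is removed).
#' @param min_maf minimum minor allele frequency (strictly greater required).
#' @param max_het maximum heterozygote proportion (strictly less required).
#' @param min_homozygosity minimum proportion of non-missing calls that are
#'   homozygous (0 or 2); strictly greater required.
#' @return filtered matrix with attribute `"filter_log"`, a named integer
#'   vector of per-rule rejection counts (a SNP can fail several rules).
#' @export
filter_snps <- function(m, max_missing = 0.5, min_maf = 0.05,
                        max_het = 0.05, min_homozygosity = 0.8) {
  stopifnot(is.matrix(m), nrow(m) >= 1L, ncol(m) >= 1L)
  n_call  <- colSums(!is.na(m))
  miss    <- colMeans(is.na(m))
  p_alt   <- colSums(m, na.rm = TRUE) / (2 * pmax(n_call, 1L))
  maf     <- pmin(p_alt, 1 - p_alt)
  het     <- colSums(m == 1, na.rm = TRUE) / pmax(n_call, 1L)
  hom     <- colSums(m == 0 | m == 2, na.rm = TRUE) / pmax(n_call, 1L)

  fail_missing <- miss >= max_missing | n_call == 0L
  fail_maf     <- maf <= min_maf
  fail_het     <- het >= max_het
  fail_hom     <- hom <= min_homozygosity
  keep <- !(fail_missing | fail_maf | fail_het | fail_hom)

  log <- c(missing      = sum(fail_missing),
           maf          = sum(fail_maf),
           het          = sum(fail_het),
           homozygosity = sum(fail_hom))
  if (!any(keep)) {
    stop("no SNPs survive filtering; rejections per rule: ",
         paste(names(log), log, sep = "=", collapse = ", "))
  }
  out <- m[, keep, drop = FALSE]
  attr(out, "filter_log") <- log
  out
}

#' Impute missing marker calls
#'
#' Replaces missing entries either by the SNP's mean code (`"mean"`, default)
#' or by an iterative low-rank SVD reconstruction (`"em_lowrank"`): starting
#' from mean fill, the matrix is repeatedly approximated by its rank-`k`
#' truncated SVD and only the missing cells are updated from the
#' approximation, until the largest change in an imputed cell falls below
#' `tol` or `max_iter` passes. Non-missing entries are never altered.
#'
#' @param m lines x SNPs matrix with possible `NA`s; every SNP needs at least
#'   one non-missing call.
#' @param method `"mean"` or `"em_lowrank"`.
#' @param rank target rank of the SVD reconstruction (em_lowrank only).
#' @param tol,max_iter convergence controls for em_lowrank.
#' @return matrix of the same shape with no missing values (real-valued
#'   imputed cells).
#' @export
impute_markers <- function(m, method = c("mean", "em_lowrank"),
                           rank = 5L, tol = 1e-4, max_iter = 50L) {
  method <- match.arg(method)
  stopifnot(is.matrix(m))
  if (!anyNA(m)) return(m)
  n_call <- colSums(!is.na(m))
  if (any(n_call == 0L)) {
    stop("SNP(s) with all calls missing: filter them out before imputing")
  }
  mu <- colMeans(m, na.rm = TRUE)
  holes <- is.na(m)
  filled <- m
  filled[holes] <- mu[col(m)[holes]]
  if (method == "mean") return(filled)

  rank <- min(rank, nrow(m) - 1L, ncol(m))
  for (it in seq_len(max_iter)) {
    sv <- svd(filled, nu = rank, nv = rank)
    approx <- sv$u %*% (sv$d[seq_len(rank)] * t(sv$v))
    delta <- max(abs(filled[holes] - approx[holes]))
    filled[holes] <- approx[holes]
    if (delta < tol) break
  }
  filled
}

#' Genomic relationship matrix
#'
#' G = M M' / r with `r` the number of markers, using the 0/1/2 codes as-is
#' by default. With `center = TRUE` columns are first centered by twice the
#' estimated allele frequency (2p), the conventional alternative.
#'
#' @param m imputed lines x SNPs matrix (no `NA`s).
#' @param center center marker columns by 2p before forming the
#'   cross-product.
#' @return symmetric lines x lines matrix with line IDs as dimnames.
#' @export
compute_grm <- function(m, center = FALSE) {
  stopifnot(is.matrix(m), ncol(m) >= 1L, !anyNA(m))
  if (center) {
    p <- colMeans(m) / 2
    m <- sweep(m, 2L, 2 * p)
  }
  g <- tcrossprod(m) / ncol(m)
  g <- (g + t(g)) / 2
  dimnames(g) <- list(rownames(m), rownames(m))
  g
}

#' Symmetric matrix square root
#'
#' Eigendecomposition-based square root of a symmetric positive semidefinite
#' kernel. Small negative eigenvalues arising from floating point are clipped
#' to zero before taking square roots, so the result `L` satisfies
#' `L %*% L == K_repaired` to Frobenius tolerance 1e-8.
#'
#' @param k symmetric matrix (checked to tolerance `sym_tol`).
#' @param sym_tol maximum allowed asymmetry `max(abs(k - t(k)))`.
#' @return symmetric matrix `L` with the same dimnames.
#' @export
matrix_sqrt <- function(k, sym_tol = 1e-8) {
  stopifnot(is.matrix(k), nrow(k) == ncol(k))
  if (max(abs(k - t(k))) > sym_tol) {
    stop("matrix is not symmetric within tolerance ", sym_tol)
  }
  e <- eigen((k + t(k)) / 2, symmetric = TRUE)
  d <- pmax(e$values, 0)
  l <- e$vectors %*% (sqrt(d) * t(e$vectors))
  l <- (l + t(l)) / 2
  dimnames(l) <- dimnames(k)
  l
}

# Clip numerically negative eigenvalues so a kernel is PSD to tolerance.
repair_psd <- function(k, tol = 1e-8) {
  e <- eigen((k + t(k)) / 2, symmetric = TRUE)
  if (min(e$values) >= -tol) return((k + t(k)) / 2)
  d <- pmax(e$values, 0)
  out <- e$vectors %*% (d * t(e$vectors))
  out <- (out + t(out)) / 2
  dimnames(out) <- dimnames(k)
  out
}

#' Read a marker matrix from CSV
#'
#' Expects lines in rows (first column = line ID) and SNPs in columns, codes
#' 0/1/2 with empty or `NA` cells for missing.
#'
#' @param path CSV file path.
#' @return numeric matrix with line IDs as rownames.
#' @export
read_markers_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1L]])
  m
}

#' Read a HapMap-like marker table
#'
#' Tab-separated, SNPs in rows and lines in columns after a set of leading
#' annotation columns (default the first column is the SNP ID and any columns
#' named in `drop` are skipped); the matrix is transposed on load so lines
#' end up in rows.
#'
#' @param path TSV path.
#' @param drop annotation column names to skip.
#' @return numeric lines x SNPs matrix.
#' @export
read_markers_hapmap <- function(path,
                                drop = c("chrom", "pos", "alleles",
                                         "strand", "assembly")) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  snp_ids <- as.character(df[[1L]])
  keep <- setdiff(names(df)[-1L], drop)
  m <- t(as.matrix(df[, keep, drop = FALSE]))
  storage.mode(m) <- "double"
  colnames(m) <- snp_ids
  m
}

#' Write a genomic relationship matrix as CSV
#'
#' Line IDs form both the header row and the first column.
#'
#' @param g square matrix with dimnames.
#' @param path output CSV path.
#' @export
write_grm_csv <- function(g, path) {
  df <- data.frame(line = rownames(g), g, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
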