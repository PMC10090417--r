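#' One-hot design matrices for environments, lines and cells
#'
#' Builds the observation-level incidence matrices with deterministic
#' (sorted) column order: `X_E` (environments), `Z_g` (lines) and `Z_gE`
#' (one column per observed line-by-environment cell). Every row of each
#' matrix sums to one.
#'
#' @param obs data.frame with `line` and `env` columns, one row per
#'   observation.
#' @return list with `X_E`, `Z_g`, `Z_gE`, and the `lines`, `envs`, `cells`
#'   level vectors.
#' @export
build_design_matrices <- function(obs) {
  stopifnot(all(c("line", "env") %in% names(obs)), nrow(obs) >= 1L)
  envf <- factor(obs$env, levels = sort(unique(obs$env)))
  linef <- factor(obs$line, levels = sort(unique(obs$line)))
  if (anyNA(envf) || anyNA(linef)) stop("unresolvable line or env ID")
  cell_key <- paste(as.character(linef), as.character(envf), sep = ":")
  cellf <- factor(cell_key, levels = sort(unique(cell_key)))
  one_hot <- function(f) {
    m <- matrix(0, length(f), nlevels(f),
                dimnames = list(NULL, levels(f)))
    m[cbind(seq_along(f), as.integer(f))] <- 1
    m
  }
  list(X_E = one_hot(envf), Z_g = one_hot(linef), Z_gE = one_hot(cellf),
       lines = levels(linef), envs = levels(envf), cells = levels(cellf))
}

#' Row-wise Khatri-Rao interaction features
#'
#' For each observation row, the flattened outer product of its `A` row and
#' `B` row, in fixed column order (a1 b1, a1 b2, ...). This is the
#' concatenated-matrix counterpart of a Hadamard kernel product.
#'
#' @param A,B numeric matrices with equal row counts.
#' @return matrix with `ncol(A) * ncol(B)` columns.
#' @export
interaction_features <- function(A, B) {
  stopifnot(is.matrix(A), is.matrix(B))
  if (nrow(A) != nrow(B)) stop("row-count mismatch: ", nrow(A), " vs ",
                               nrow(B))
  out <- matrix(0, nrow(A), ncol(A) * ncol(B))
  for (j in seq_len(ncol(A))) {
    out[, ((j - 1L) * ncol(B) + 1L):(j * ncol(B))] <- A[, j] * B
  }
  ca <- if (is.null(colnames(A))) paste0("a", seq_len(ncol(A))) else
    colnames(A)
  cb <- if (is.null(colnames(B))) paste0("b", seq_len(ncol(B))) else
    colnames(B)
  colnames(out) <- as.vector(t(outer(ca, cb, paste, sep = ":")))
  out
}

# column standardization with a stored round-trippable record
standardize_block <- function(m) {
  mu <- colMeans(m)
  sd_ <- apply(m, 2L, stats::sd)
  sd_[sd_ == 0 | !is.finite(sd_)] <- 1
  list(x = sweep(sweep(m, 2L, mu), 2L, sd_, "/"), center = mu, scale = sd_)
}

#' The nine multi-source predictor sets (and the environment-free LOEO set)
#'
#' Assembles a named predictor set in two matched views:
#'
#' * the concatenated-matrix (PLS) view, following the printed block lists:
#'   ETA1 `[X_E, X_g L_g]`; ETA2 `[..., H]`; ETA3 `[..., H, X_gE L_gE]`;
#'   ETA4 `[..., H, X_gE L_gE, X_g L_g : H]`; ETA5-ETA7 the same with `I` in
#'   place of `H`; ETA8 `[X_E, H]`; ETA9 `[X_E, I]` — where
#'   `L_g = G^0.5` and `L_gE = K_gE^0.5` with
#'   `K_gE = (Z_g G Z_g') * (X_E X_E')` (elementwise) restricted to observed
#'   cells;
#' * the kernel-list (GBLUP) view: environment block as fixed one-hot,
#'   kernels `K_g = Z_g G Z_g'`, `K_gE` as above, `K_H = H H'/11`,
#'   `K_I = I I'/3` (columns standardized first) and Hadamard products
#'   `K_g * K_H`, `K_g * K_I` for the interactions.
#'
#' The environment-free ids `g`, `H`, `I`, `gH` (= g + H + gE) and `gI`
#' (= g + I + gE) support leave-one-environment-out runs, where the held-out
#' environment's one-hot column would carry no information.
#'
#' `H` and `I` columns are standardized (mean 0, sd 1) before concatenation
#' and kernel construction; incidence blocks are left as 0/1.
#'
#' @param eta_id one of `ETA1`..`ETA9`, `g`, `H`, `I`, `gH`, `gI`.
#' @param grm line-by-line genomic relationship matrix covering every line
#'   in `obs` (dimnames = line IDs).
#' @param obs data.frame with `line`, `env` (one row per observation).
#' @param features data.frame with `line`, `env` and the 11 `H` columns
#'   (required for H/I-based sets), aligned by (line, env) match.
#' @return list of class `predictor_set` with `eta_id`, `blocks` (named PLS
#'   blocks), `X` (their concatenation), `fixed` (GBLUP fixed one-hot),
#'   `kernels` (named kernel list), `standardization`, `designs`.
#' @export
build_predictor <- function(eta_id, grm, obs, features = NULL) {
  terms_of <- list(
    ETA1 = c("E", "g"),
    ETA2 = c("E", "g", "H"),
    ETA3 = c("E", "g", "H", "gE"),
    ETA4 = c("E", "g", "H", "gE", "gxH"),
    ETA5 = c("E", "g", "I"),
    ETA6 = c("E", "g", "I", "gE"),
    ETA7 = c("E", "g", "I", "gE", "gxI"),
    ETA8 = c("E", "H"),
    ETA9 = c("E", "I"),
    g  = "g", H = "H", I = "I",
    gH = c("g", "H", "gE"), gI = c("g", "I", "gE"))
  if (!eta_id %in% names(terms_of)) stop("unknown eta_id: ", eta_id)
  terms <- terms_of[[eta_id]]

  d <- build_design_matrices(obs)
  if (!all(d$lines %in% rownames(grm))) {
    stop("GRM does not cover line(s): ",
         paste(utils::head(setdiff(d$lines, rownames(grm))), collapse = ", "))
  }
  G <- grm[d$lines, d$lines, drop = FALSE]

  needs_feat <- any(c("H", "I", "gxH", "gxI") %in% terms)
  std <- list()
  Hs <- Is <- NULL
  if (needs_feat) {
    if (is.null(features)) {
      stop("predictor ", eta_id, " needs multispectral features")
    }
    idx <- match(paste(obs$line, obs$env),
                 paste(features$line, features$env))
    if (anyNA(idx)) stop("features missing for some observations")
    Hraw <- as.matrix(features[idx, H_NAMES, drop = FALSE])
    sH <- standardize_block(Hraw)
    Hs <- sH$x
    std$H <- sH[c("center", "scale")]
    Is <- Hs[, I_NAMES, drop = FALSE]
  }

  Kg <- d$Z_g %*% G %*% t(d$Z_g)
  KE_inc <- tcrossprod(d$X_E)
  KgE <- Kg * KE_inc

  blocks <- list()
  kernels <- list()
  for (tm in terms) {
    switch(tm,
      E = { blocks$X_E <- d$X_E },
      g = {
        Lg <- matrix_sqrt(repair_psd(G))
        blocks$X_gL_g <- d$Z_g %*% Lg
        kernels$K_g <- Kg
      },
      H = { blocks$H <- Hs; kernels$K_H <- tcrossprod(Hs) / ncol(Hs) },
      I = { blocks$I <- Is; kernels$K_I <- tcrossprod(Is) / ncol(Is) },
      gE = {
        LgE <- matrix_sqrt(repair_psd(KgE))
        # Z_gE maps observations to cells; with one observation per cell the
        # observation-level KgE and its square root coincide with the
        # cell-restricted form
        blocks$X_gEL_gE <- LgE
        kernels$K_gE <- KgE
      },
      gxH = {
        blocks$X_gL_g_H <- interaction_features(blocks$X_gL_g, Hs)
        kernels$K_gxH <- Kg * kernels$K_H
      },
      gxI = {
        blocks$X_gL_g_I <- interaction_features(blocks$X_gL_g, Is)
        kernels$K_gxI <- Kg * kernels$K_I
      })
  }
  kernels <- lapply(kernels, repair_psd)

  X <- do.call(cbind, blocks)
  rownames(X) <- NULL
  structure(list(eta_id = eta_id, terms = terms, blocks = blocks,
                 X = X,
                 fixed = if ("E" %in% terms) d$X_E else
                   matrix(1, nrow(obs), 1L,
                          dimnames = list(NULL, "(Intercept)")),
                 kernels = kernels, standardization = std, designs = d),
            class = "predictor_set")
}
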