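# Penalized spline bases for the density GAM.
#
# Basis family: cubic B-splines with second-order difference penalties;
# multidimensional smooths are tensor products of marginal B-spline bases.
# The contract is the penalty structure and the functional-ANOVA
# decomposition (interaction smooths exclude the main effects they interact
# with), not the particular basis. Covariates are standardized to zero mean
# and unit SD before basis construction so the 2-D spatial smooth is
# (effectively) isotropic and the design is well conditioned.

#' Model term constructors
#'
#' A model specification is an ordered list of terms on the log scale, always
#' including an intercept. The menu mirrors the standard density-surface
#' model family: `M0` spatial smooth only; `M1` adds a smooth of year; `M2`
#' adds a space-by-year interaction tensor smooth; `M3` adds a year random
#' effect to `M1`; `M4` is spatial smooth plus year random effect. Observer
#' random effects and a fixed survey factor can be appended to any of them.
#'
#' @param k marginal basis dimension. For `term_spatial` the 2-D smooth uses
#'   `k x k` tensor columns (default 6, i.e. 36 columns before the
#'   sum-to-zero constraint); for `term_temporal` a single margin (default
#'   15, enough headroom for several full cycles in a 25-year series); for
#'   `term_tensor`, `k_space` per spatial coordinate and `k_year` for the
#'   year margin (defaults 4 and 5).
#' @return a term specification list.
#' @name model_terms
NULL

#' @rdname model_terms
#' @export
term_spatial <- function(k = 6) {
  stopifnot(k >= 3)
  list(label = "s(X,Y)", type = "spatial", k = k)
}

#' @rdname model_terms
#' @export
term_temporal <- function(k = 15) {
  stopifnot(k >= 3)
  list(label = "s(Year)", type = "temporal", k = k)
}

#' @rdname model_terms
#' @param k_space,k_year marginal dimensions of the interaction tensor.
#' @export
term_tensor <- function(k_space = 4, k_year = 5) {
  stopifnot(k_space >= 3, k_year >= 3)
  list(label = "ti(X,Y,Year)", type = "tensor", k_space = k_space,
       k_year = k_year)
}

#' @rdname model_terms
#' @export
term_year_re <- function() list(label = "s(fYear)", type = "year_re")

#' @rdname model_terms
#' @export
term_observer_re <- function() list(label = "s(Observer)", type = "observer_re")

#' @rdname model_terms
#' @export
term_survey <- function() list(label = "Survey", type = "survey")

#' Assemble a model specification
#'
#' @param ... term objects from [model_terms].
#' @return `nbgam_spec` object.
#' @export
model_spec <- function(...) {
  terms <- list(...)
  types <- vapply(terms, `[[`, "", "type")
  if (anyDuplicated(types)) stop("duplicate term types in model spec", call. = FALSE)
  if ("tensor" %in% types && !all(c("spatial", "temporal") %in% types))
    stop("the interaction tensor requires both main-effect smooths", call. = FALSE)
  structure(list(terms = terms), class = "nbgam_spec")
}

#' Standard model menu
#'
#' @param name one of `"M0"`..`"M4"`.
#' @param observer append an observer random effect.
#' @param survey append a fixed survey factor.
#' @param k_spatial,k_temporal marginal basis dimensions passed through.
#' @export
model_preset <- function(name, observer = FALSE, survey = FALSE,
                         k_spatial = 6, k_temporal = 15) {
  terms <- switch(name,
    M0 = list(term_spatial(k_spatial)),
    M1 = list(term_spatial(k_spatial), term_temporal(k_temporal)),
    M2 = list(term_spatial(k_spatial), term_temporal(k_temporal), term_tensor()),
    M3 = list(term_spatial(k_spatial), term_temporal(k_temporal), term_year_re()),
    M4 = list(term_spatial(k_spatial), term_year_re()),
    stop(sprintf("unknown model preset '%s' (use M0..M4)", name), call. = FALSE))
  if (observer) terms <- c(terms, list(term_observer_re()))
  if (survey) terms <- c(terms, list(term_survey()))
  do.call(model_spec, terms)
}

# ---- basis building blocks ------------------------------------------------

# Cubic B-spline basis on equally spaced knots covering the (slightly
# extended) data range; k columns. Returns basis matrix and the knot vector.
bsp_basis <- function(x, k, knots = NULL) {
  ord <- 4
  if (is.null(knots)) {
    r <- range(x)
    if (diff(r) <= 0) r <- r + c(-0.5, 0.5)
    pad <- 0.1 * diff(r)
    lo <- r[1] - pad; hi <- r[2] + pad
    nb <- k - 2                      # interior+boundary breakpoints
    if (nb < 2) stop("basis dimension too small", call. = FALSE)
    h <- (hi - lo) / (nb - 1)
    knots <- c(lo - (3:1) * h, seq(lo, hi, length.out = nb), hi + (1:3) * h)
  }
  X <- splines::splineDesign(knots, x, ord = ord, outer.ok = TRUE)
  list(X = X, knots = knots)
}

# Second-order difference penalty for a k-column B-spline basis.
diff_penalty <- function(k, order = 2) {
  D <- diff(diag(k), differences = order)
  crossprod(D)
}

# Row-wise Kronecker product; column (i-1)*ncol(B)+j is A[,i]*B[,j], matching
# kronecker() ordering for the penalties.
rowkron <- function(A, B) {
  out <- matrix(0, nrow(A), ncol(A) * ncol(B))
  q <- ncol(B)
  for (i in seq_len(ncol(A))) out[, (i - 1) * q + seq_len(q)] <- A[, i] * B
  out
}

# 0/1 indicator columns, one per factor level; NA rows stay all-zero
indicator_matrix <- function(f, nlev) {
  X <- matrix(0, length(f), nlev)
  ok <- !is.na(f)
  X[cbind(which(ok), as.integer(f)[ok])] <- 1
  X
}

# Absorb a single linear constraint c'beta = 0 by reparameterization
# X -> X Z, S -> Z' S Z with Z an orthonormal basis of the null space of c.
constraint_Z <- function(cvec) {
  qr.Q(qr(matrix(cvec, ncol = 1)), complete = TRUE)[, -1, drop = FALSE]
}

scaleS <- function(S) {
  d <- mean(diag(S))
  if (d <= 0) S else S / d
}

std_params <- function(x) {
  s <- stats::sd(x)
  list(mean = mean(x), sd = if (is.finite(s) && s > 0) s else 1)
}
apply_std <- function(x, p) (x - p$mean) / p$sd

# ---- term builders --------------------------------------------------------
# Each builder returns list(X, S = list of term-local penalty matrices,
# penalized = logical per column block, meta = everything needed to rebuild
# the same columns for new data).

build_term <- function(term, data, meta = NULL) {
  switch(term$type,
    spatial = {
      if (is.null(meta)) {
        meta <- list(sx = std_params(data$x_c), sy = std_params(data$y_c))
        bx <- bsp_basis(apply_std(data$x_c, meta$sx), term$k)
        by <- bsp_basis(apply_std(data$y_c, meta$sy), term$k)
        meta$kx <- bx$knots; meta$ky <- by$knots
        Xt <- rowkron(bx$X, by$X)
        k <- term$k
        S <- scaleS(kronecker(diff_penalty(k), diag(k)) +
                      kronecker(diag(k), diff_penalty(k)))
        meta$Z <- constraint_Z(colMeans(Xt))
        meta$S <- crossprod(meta$Z, S %*% meta$Z)
      } else {
        bx <- bsp_basis(apply_std(data$x_c, meta$sx), term$k, meta$kx)
        by <- bsp_basis(apply_std(data$y_c, meta$sy), term$k, meta$ky)
        Xt <- rowkron(bx$X, by$X)
      }
      list(X = Xt %*% meta$Z, S = list(meta$S), meta = meta)
    },
    temporal = {
      if (is.null(meta)) {
        meta <- list(st = std_params(data$year))
        bt <- bsp_basis(apply_std(data$year, meta$st), term$k)
        meta$kt <- bt$knots
        Xt <- bt$X
        S <- scaleS(diff_penalty(term$k))
        meta$Z <- constraint_Z(colMeans(Xt))
        meta$S <- crossprod(meta$Z, S %*% meta$Z)
      } else {
        Xt <- bsp_basis(apply_std(data$year, meta$st), term$k, meta$kt)$X
      }
      list(X = Xt %*% meta$Z, S = list(meta$S), meta = meta)
    },
    tensor = {
      ks <- term$k_space; kt <- term$k_year
      if (is.null(meta)) {
        meta <- list(sx = std_params(data$x_c), sy = std_params(data$y_c),
                     st = std_params(data$year))
        bx <- bsp_basis(apply_std(data$x_c, meta$sx), ks)
        by <- bsp_basis(apply_std(data$y_c, meta$sy), ks)
        bt <- bsp_basis(apply_std(data$year, meta$st), kt)
        meta$kx <- bx$knots; meta$ky <- by$knots; meta$kt <- bt$knots
        Xs <- rowkron(bx$X, by$X)
        Ss <- scaleS(kronecker(diff_penalty(ks), diag(ks)) +
                       kronecker(diag(ks), diff_penalty(ks)))
        meta$Zs <- constraint_Z(colMeans(Xs))
        Ss <- crossprod(meta$Zs, Ss %*% meta$Zs)
        Xt <- bt$X
        St <- scaleS(diff_penalty(kt))
        meta$Zt <- constraint_Z(colMeans(Xt))
        St <- crossprod(meta$Zt, St %*% meta$Zt)
        ps <- ncol(meta$Zs); pt <- ncol(meta$Zt)
        meta$S1 <- scaleS(kronecker(Ss, diag(pt)))   # spatial-margin roughness
        meta$S2 <- scaleS(kronecker(diag(ps), St))   # year-margin roughness
      }
      bx <- bsp_basis(apply_std(data$x_c, meta$sx), ks, meta$kx)
      by <- bsp_basis(apply_std(data$y_c, meta$sy), ks, meta$ky)
      bt <- bsp_basis(apply_std(data$year, meta$st), kt, meta$kt)
      Xs <- rowkron(bx$X, by$X) %*% meta$Zs
      Xt <- bt$X %*% meta$Zt
      list(X = rowkron(Xs, Xt), S = list(meta$S1, meta$S2), meta = meta)
    },
    year_re = {
      if (is.null(meta)) meta <- list(levels = sort(unique(data$year)))
      f <- factor(data$year, levels = meta$levels)
      # unseen years keep an all-zero row: the effect sits at its prior mean
      X <- indicator_matrix(f, length(meta$levels))
      list(X = X, S = list(diag(length(meta$levels))), meta = meta,
           new_levels = anyNA(f))
    },
    observer_re = {
      if (is.null(meta)) {
        if (is.null(data$observer) || all(is.na(data$observer)))
          stop("observer random effect requires an observer column", call. = FALSE)
        meta <- list(levels = sort(unique(stats::na.omit(data$observer))))
      }
      f <- factor(data$observer, levels = meta$levels)
      if (anyNA(f)) stop("unknown observer level in data", call. = FALSE)
      X <- indicator_matrix(f, length(meta$levels))
      list(X = X, S = list(diag(length(meta$levels))), meta = meta)
    },
    survey = {
      if (is.null(meta)) {
        if (is.null(data$survey_id))
          stop("survey factor requires a survey_id column", call. = FALSE)
        meta <- list(levels = sort(unique(data$survey_id)))
      }
      f <- factor(data$survey_id, levels = meta$levels)
      if (anyNA(f)) stop("unknown survey level in data", call. = FALSE)
      # treatment coding: first level is the baseline (intercept)
      X <- indicator_matrix(f, length(meta$levels))[, -1, drop = FALSE]
      list(X = X, S = list(), meta = meta)
    },
    stop("unknown term type: ", term$type))
}

# Build the full design: intercept + one block per term.
# info = NULL for fitting (metadata computed from data); pass a previous
# build's info for prediction on new data.
build_design <- function(spec, data, info = NULL) {
  fitting <- is.null(info)
  if (fitting) info <- list(metas = vector("list", length(spec$terms)))
  X <- matrix(1, nrow(data), 1)
  term_map <- list(`(Intercept)` = 1L)
  S_full <- list()
  S_labels <- character(0)
  new_year_levels <- FALSE
  for (i in seq_along(spec$terms)) {
    tm <- spec$terms[[i]]
    bt <- build_term(tm, data, meta = info$metas[[i]])
    if (fitting) info$metas[[i]] <- bt$meta
    cols <- ncol(X) + seq_len(ncol(bt$X))
    term_map[[tm$label]] <- cols
    X <- cbind(X, bt$X)
    if (isTRUE(bt$new_levels)) new_year_levels <- TRUE
    for (j in seq_along(bt$S)) {
      S_labels <- c(S_labels,
                    if (length(bt$S) > 1) sprintf("%s[%d]", tm$label, j)
                    else tm$label)
      S_full[[length(S_full) + 1]] <- list(cols = cols, S = bt$S[[j]])
    }
  }
  list(X = X, term_map = term_map, S = S_full, S_labels = S_labels,
       info = info, new_year_levels = new_year_levels)
}

# Embed a term-local penalty into the full coefficient space.
embed_S <- function(Sitem, p) {
  S <- matrix(0, p, p)
  S[Sitem$cols, Sitem$cols] <- Sitem$S
  S
}
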