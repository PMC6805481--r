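## Mixed-model engine: model specification, AI-REML with EM fallback, and
## BLUP solving. One engine serves the pedigree animal/repeatability models,
## GBLUP, ssGBLUP and GFBLUP.
##
## Two computational routes share the same interface:
##  * the Henderson mixed-model-equations route, used when every random term
##    supplies (or implies) an inverse covariance -- pedigree A inverse,
##    single-step H inverse, i.i.d. terms; the dense covariance is never
##    formed;
##  * the phenotypic-covariance (V) route, used when a term supplies a dense
##    covariance that may be singular, as the VanRaden G built from observed
##    allele frequencies always is (the centred marker matrix annihilates
##    the ones vector). V = sum sigma2_i Z K Z' + sigma2_e I stays positive
##    definite, so no covariance inverse is ever needed.

#' Define a random term for a mixed model
#'
#' A term is `Z u` with `u ~ N(0, K sigma2)`. The covariance among levels is
#' given either as a dense matrix `K` (with level ids as dimnames, possibly
#' singular), as its inverse `Kinv` (dense or sparse, e.g. a pedigree A
#' inverse or an assembled single-step H inverse), or omitted for i.i.d.
#' levels (K = I).
#'
#' @param label short name for the term (e.g. `"g"`, `"pe"`, `"litter"`).
#' @param ids character vector, one entry per record, naming the level each
#'   record belongs to. Levels that receive no record (e.g. validation
#'   animals inside G) are still predicted through the covariance.
#' @param K dense covariance matrix among levels, or `NULL`.
#' @param Kinv inverse covariance (dense or `Matrix` sparse), or `NULL`.
#' @param levels explicit level ordering; defaults to `rownames(K)`/
#'   `rownames(Kinv)` or the unique record ids for i.i.d. terms.
#' @return object of class `mme_term`.
#' @export
random_term <- function(label, ids, K = NULL, Kinv = NULL, levels = NULL) {
  .check(is.character(label) && length(label) == 1L, "label must be a string")
  .check(is.null(K) || is.null(Kinv), "give K or Kinv, not both")
  ids <- as.character(ids)
  if (is.null(levels)) {
    levels <- if (!is.null(K)) rownames(K)
              else if (!is.null(Kinv)) rownames(Kinv)
              else unique(ids)
  }
  .check(!is.null(levels), "term covariance needs level ids as dimnames")
  .check(all(ids %in% levels),
         sprintf("term '%s': some record ids are not covariance levels", label))
  structure(list(label = label, ids = ids, K = K, Kinv = Kinv,
                 levels = as.character(levels)),
            class = "mme_term")
}

#' Specify a mixed model
#'
#' @param y numeric response vector (one entry per record).
#' @param X fixed-effect design matrix (defaults to an intercept column).
#' @param random list of [random_term()] objects.
#' @return object of class `mme_model`.
#' @export
mme_model <- function(y, X = NULL, random = list()) {
  y <- as.numeric(y)
  n <- length(y)
  .check(n >= 2, "need at least two records")
  .check(!anyNA(y), "response contains NA")
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  .check(nrow(X) == n, "X must have one row per record")
  .check(length(random) >= 1, "at least one random term is required")
  for (tm in random) {
    .check(inherits(tm, "mme_term"), "random terms must come from random_term()")
    .check(length(tm$ids) == n, sprintf(
      "term '%s': ids length differs from number of records", tm$label))
  }
  labs <- vapply(random, `[[`, "", "label")
  .check(!anyDuplicated(labs), "random term labels must be unique")
  ## rank-deficient fixed designs raise an error naming the aliased columns
  ## so confounded herd-year-season levels are visible, not silently dropped
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("fixed-effect design is rank deficient; aliased columns: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  structure(list(y = y, X = X, random = random), class = "mme_model")
}

## Precompute per-term machinery. Route "mme" terms carry Kinv and
## logdet(K); route "V" terms carry K and the record-space product Z K Z'.
.prep_terms <- function(model) {
  n <- length(model$y)
  terms <- lapply(model$random, function(tm) {
    q <- length(tm$levels)
    j <- match(tm$ids, tm$levels)
    Z <- Matrix::sparseMatrix(i = seq_len(n), j = j, x = 1, dims = c(n, q))
    out <- list(label = tm$label, Z = Z, q = q, levels = tm$levels,
                iid = is.null(tm$K) && is.null(tm$Kinv))
    if (!is.null(tm$Kinv)) {
      out$Kinv <- tm$Kinv
      ld <- if (inherits(tm$Kinv, "Matrix"))
        as.numeric(Matrix::determinant(tm$Kinv, logarithm = TRUE)$modulus)
      else determinant(as.matrix(tm$Kinv), logarithm = TRUE)$modulus
      out$logdetK <- -as.numeric(ld)
    } else if (!is.null(tm$K)) {
      K <- as.matrix(tm$K)
      class(K) <- NULL          # plain matrix: keeps Matrix dispatch sane
      out$K <- K
    } else {
      out$Kinv <- Matrix::Diagonal(q)
      out$logdetK <- 0
      out$K <- NULL
    }
    out
  })
  route <- if (all(vapply(terms, function(t) !is.null(t$Kinv), TRUE)))
    "mme" else "V"
  if (route == "V") {
    for (i in seq_along(terms)) {
      t <- terms[[i]]
      if (!is.null(t$Kinv)) {        # mixed case: densify this covariance
        terms[[i]]$K <- chol2inv(chol(as.matrix(t$Kinv)))
      } else if (t$iid) {
        terms[[i]]$K <- diag(t$q)
      }
      ZK <- as.matrix(terms[[i]]$Z %*% terms[[i]]$K)
      terms[[i]]$ZK <- ZK
      terms[[i]]$ZKZ <- .symmetrize(tcrossprod(ZK, as.matrix(terms[[i]]$Z)))
    }
  }
  attr(terms, "route") <- route
  terms
}

## ---- Henderson MME route ------------------------------------------------

.build_mme <- function(X, terms, s2, s2e) {
  W <- cbind(Matrix::Matrix(X, sparse = TRUE),
             do.call(cbind, lapply(terms, `[[`, "Z")))
  WtW <- as.matrix(Matrix::crossprod(W))
  p <- ncol(X)
  offs <- p + c(0, cumsum(vapply(terms, `[[`, 0, "q")))
  Cs <- WtW
  for (i in seq_along(terms)) {
    idx <- (offs[i] + 1):offs[i + 1]
    Cs[idx, idx] <- Cs[idx, idx] + as.matrix(terms[[i]]$Kinv) * (s2e / s2[i])
  }
  list(Cs = Cs, W = W, p = p, offs = offs)
}

## One full REML evaluation on the MME route at (s2, s2e): solutions,
## -2 logLik (up to an additive constant), per-term quadratics/traces.
.reml_eval_mme <- function(model, terms, s2, s2e) {
  y <- model$y
  n <- length(y)
  b <- .build_mme(model$X, terms, s2, s2e)
  ch <- tryCatch(chol(b$Cs), error = function(e)
    stop("mixed model equations are singular: ", conditionMessage(e),
         call. = FALSE))
  rhs <- as.numeric(Matrix::crossprod(b$W, y))
  theta <- backsolve(ch, backsolve(ch, rhs, transpose = TRUE))
  Cinv <- chol2inv(ch)
  yPy <- (sum(y * y) - sum(theta * rhs)) / s2e
  logdetCs <- 2 * sum(log(diag(ch)))
  m <- nrow(b$Cs)
  qv <- vapply(terms, `[[`, 0, "q")
  neg2ll <- (n - m) * log(s2e) + sum(qv * log(s2)) +
    sum(vapply(terms, `[[`, 0, "logdetK")) + logdetCs + yPy
  K <- length(terms)
  u <- vector("list", K)
  S <- Tt <- numeric(K)
  for (i in seq_len(K)) {
    idx <- (b$offs[i] + 1):b$offs[i + 1]
    u[[i]] <- theta[idx]
    Kinv <- terms[[i]]$Kinv
    S[i] <- as.numeric(crossprod(u[[i]], as.matrix(Kinv %*% u[[i]])))
    Tt[i] <- s2e * sum(as.matrix(Kinv) * Cinv[idx, idx])
  }
  resid <- y - as.numeric(b$W %*% theta)
  ## score and EM proposal from the MME statistics
  p <- b$p
  score <- c(-0.5 * ((qv - Tt / s2) / s2 - S / s2^2),
             -0.5 * ((n - p - sum(qv - Tt / s2)) / s2e -
                       sum(resid^2) / s2e^2))
  em <- c((S + Tt) / qv, sum(y * resid) / (n - p))
  ## AI working vectors: f_i = Z_i u_i / s2_i, f_e = resid / s2e;
  ## P f = (f - W C^-1 W' f / s2e) / s2e
  Fmat <- matrix(0, n, K + 1)
  for (i in seq_len(K))
    Fmat[, i] <- as.numeric(terms[[i]]$Z %*% u[[i]]) / s2[i]
  Fmat[, K + 1] <- resid / s2e
  Theta <- Cinv %*% as.matrix(Matrix::crossprod(b$W, Fmat))
  PF <- (Fmat - as.matrix(b$W %*% Theta)) / s2e
  AI <- .symmetrize(0.5 * crossprod(Fmat, PF))
  pev <- lapply(seq_len(K), function(i) {
    idx <- (b$offs[i] + 1):b$offs[i + 1]
    diag(Cinv)[idx] * s2e
  })
  list(beta = theta[seq_len(p)], u = u, resid = resid, neg2ll = neg2ll,
       score = score, em = em, AI = AI, pev = pev)
}

## ---- phenotypic-covariance (V) route ------------------------------------

.reml_eval_V <- function(model, terms, s2, s2e) {
  y <- model$y
  X <- model$X
  n <- length(y)
  p <- ncol(X)
  K <- length(terms)
  V <- diag(s2e, n)
  for (i in seq_len(K)) V <- V + s2[i] * terms[[i]]$ZKZ
  ch <- chol(V)
  Vinv <- chol2inv(ch)
  if (p > 0) {
    XtVi <- crossprod(X, Vinv)
    XtViX <- XtVi %*% X
    chx <- chol(XtViX)
    bhat <- backsolve(chx, backsolve(chx, XtVi %*% y, transpose = TRUE))
    P <- .symmetrize(Vinv - crossprod(XtVi, chol2inv(chx) %*% XtVi))
    logdet_xvx <- 2 * sum(log(diag(chx)))
  } else {
    bhat <- numeric(0)
    P <- Vinv
    logdet_xvx <- 0
  }
  Py <- as.numeric(P %*% y)
  yPy <- sum(y * Py)
  neg2ll <- 2 * sum(log(diag(ch))) + logdet_xvx + yPy
  qv <- vapply(terms, `[[`, 0, "q")
  score <- numeric(K + 1)
  Fmat <- matrix(0, n, K + 1)
  for (i in seq_len(K)) {
    Vi <- terms[[i]]$ZKZ
    ViPy <- as.numeric(Vi %*% Py)
    score[i] <- -0.5 * (sum(P * Vi) - sum(Py * ViPy))
    Fmat[, i] <- ViPy
  }
  score[K + 1] <- -0.5 * (sum(diag(P)) - sum(Py * Py))
  Fmat[, K + 1] <- Py
  AI <- .symmetrize(0.5 * crossprod(Fmat, P %*% Fmat))
  ## EM-style update expressed through P (exact EM when K is nonsingular)
  em <- c(s2 + (s2^2 / qv) * 2 * score[seq_len(K)],
          s2e + (s2e^2 / n) * 2 * score[K + 1])
  u <- lapply(seq_len(K), function(i)
    s2[i] * as.numeric(crossprod(terms[[i]]$ZK, Py)))
  fitted <- as.numeric(X %*% bhat) +
    Reduce(`+`, lapply(seq_len(K), function(i)
      as.numeric(terms[[i]]$Z %*% u[[i]])))
  pev <- lapply(seq_len(K), function(i) {
    ZK <- terms[[i]]$ZK
    s2[i] * diag(terms[[i]]$K) -
      s2[i]^2 * colSums(ZK * (P %*% ZK))
  })
  list(beta = as.numeric(bhat), u = u, resid = y - fitted, neg2ll = neg2ll,
       score = score, em = em, AI = AI, pev = pev)
}

.reml_eval <- function(model, terms, s2, s2e) {
  if (attr(terms, "route") == "mme") .reml_eval_mme(model, terms, s2, s2e)
  else .reml_eval_V(model, terms, s2, s2e)
}

#' REML variance-component estimation
#'
#' Average-information REML with EM-REML fallback: at each iteration the AI
#' update is attempted; if it proposes a variance below the floor, fails to
#' solve, or decreases the restricted likelihood, the (monotone) EM update
#' is used instead. Convergence requires a relative log-likelihood change
#' below `tol_loglik` and a maximum relative parameter change below
#' `tol_par`.
#'
#' @param model an [mme_model()].
#' @param init optional named starting values (one per random term plus
#'   `"e"`); default splits the phenotypic variance evenly.
#' @param max_iter maximum iterations before an error is raised.
#' @param tol_loglik,tol_par convergence tolerances.
#' @param verbose print the iteration trace.
#' @return object of class `variance_components`: `sigma2` (named vector
#'   with the residual as `"e"`), `loglik` trace (restricted log-likelihood
#'   up to a constant), `iterations`, `converged`, `steps` (step type per
#'   iteration), `h2` (share of each term in the total variance).
#' @export
reml <- function(model, init = NULL, max_iter = 200L,
                 tol_loglik = 1e-8, tol_par = 1e-6, verbose = FALSE) {
  .check(inherits(model, "mme_model"), "model must come from mme_model()")
  terms <- .prep_terms(model)
  K <- length(terms)
  labs <- vapply(terms, `[[`, "", "label")
  n <- length(model$y)
  p <- ncol(model$X)
  .check(n >= p + 2, "too few records for the fixed effects")
  vy <- stats::var(model$y)
  floor_v <- 1e-8 * vy
  if (is.null(init)) {
    s2 <- rep(vy / (K + 1), K)
    s2e <- vy / (K + 1)
  } else {
    .check(all(c(labs, "e") %in% names(init)), "init must name every term and 'e'")
    s2 <- pmax(as.numeric(init[labs]), floor_v)
    s2e <- max(as.numeric(init["e"]), floor_v)
  }
  ev <- .reml_eval(model, terms, s2, s2e)
  ll <- -0.5 * ev$neg2ll
  trace_ll <- ll
  steps <- character(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    cur <- c(s2, s2e)
    em_prop <- pmax(ev$em, floor_v)
    ## active set: components parked at the floor with a downhill gradient
    ## are frozen there and excluded from the Newton system
    act <- !(cur <= 2 * floor_v & ev$score < 0)
    dir <- rep(0, K + 1)
    dir_act <- if (any(act))
      tryCatch(solve(ev$AI[act, act, drop = FALSE], ev$score[act]),
               error = function(e) NULL) else numeric(0)
    if (is.null(dir_act)) dir <- NULL else dir[act] <- dir_act
    prop <- NULL; ev_new <- NULL; used <- NULL
    if (!is.null(dir) && all(is.finite(dir))) {
      ## damped AI: full Newton step, halved until the likelihood improves
      for (damp in c(1, 0.5, 0.25, 0.1)) {
        cand <- pmax(cur + damp * dir, floor_v)
        ev_c <- tryCatch(
          .reml_eval(model, terms, cand[seq_len(K)], cand[K + 1]),
          error = function(e) NULL)
        if (!is.null(ev_c) && -0.5 * ev_c$neg2ll >= ll - 1e-10) {
          prop <- cand; ev_new <- ev_c; used <- "AI"
          break
        }
      }
    }
    if (is.null(prop)) {
      ## EM with extrapolation: a boundary component shrinks geometrically
      ## under plain EM, so try lengthened EM steps first and keep the best
      ## likelihood (plain EM is monotone and always available)
      best <- list(prop = em_prop,
                   ev = .reml_eval(model, terms, em_prop[seq_len(K)],
                                   em_prop[K + 1]))
      for (alpha in c(8, 4, 2)) {
        cand <- pmax(cur + alpha * (em_prop - cur), floor_v)
        ev_c <- tryCatch(
          .reml_eval(model, terms, cand[seq_len(K)], cand[K + 1]),
          error = function(e) NULL)
        if (!is.null(ev_c) && ev_c$neg2ll < best$ev$neg2ll) {
          best <- list(prop = cand, ev = ev_c)
          break
        }
      }
      prop <- best$prop
      ev_new <- best$ev
      used <- "EM"
    }
    .check(!is.null(ev_new), "REML evaluation failed")
    ll_new <- -0.5 * ev_new$neg2ll
    rel_ll <- abs(ll_new - ll) / (abs(ll) + 1)
    ## parameter-change criterion ignores components parked at the floor
    active <- prop > 2 * floor_v | cur > 2 * floor_v
    rel_par <- if (any(active))
      max(abs(prop - cur)[active] / (abs(cur)[active] + 1e-12)) else 0
    ## boundary (KKT) state: at the floor with a downhill gradient
    at_bound <- prop <= 2 * floor_v & ev_new$score < 0
    grad_ok <- all(abs(ev_new$score * prop) < 1e-4 * (1 + abs(ll_new)) |
                     at_bound)
    s2 <- prop[seq_len(K)]; s2e <- prop[K + 1]
    ev <- ev_new; ll <- ll_new
    trace_ll <- c(trace_ll, ll)
    steps <- c(steps, used)
    if (verbose)
      message(sprintf("iter %d [%s] logL = %.6f  sigma2 = %s", it, used, ll,
                      paste(signif(c(s2, s2e), 5), collapse = " ")))
    if (rel_ll < tol_loglik && (rel_par < tol_par || grad_ok)) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    stop("REML did not converge in ", max_iter, " iterations; trace: ",
         paste(signif(trace_ll, 8), collapse = " "), call. = FALSE)
  sigma2 <- stats::setNames(c(s2, s2e), c(labs, "e"))
  structure(list(sigma2 = sigma2, loglik = trace_ll, iterations = length(steps),
                 converged = converged, steps = steps,
                 h2 = sigma2[labs] / sum(sigma2)),
            class = "variance_components")
}

#' @exportS3Method base::print
print.variance_components <- function(x, ...) {
  cat("REML variance components (", x$iterations, " iterations, ",
      if (x$converged) "converged" else "NOT converged", ")\n", sep = "")
  print(signif(x$sigma2, 6))
  invisible(x)
}

#' Solve for BLUP at fixed variance components
#'
#' Uses Henderson's mixed model equations when every term carries an inverse
#' covariance (for single-step models pass the assembled H inverse as the
#' `g` term's `Kinv`; the dense H is never formed), and the equivalent
#' phenotypic-covariance solve when a dense, possibly singular covariance is
#' given.
#'
#' @param model an [mme_model()].
#' @param vc a `variance_components` object or a named numeric vector of
#'   variances (per term label, plus `"e"`).
#' @param pev if `TRUE`, return the prediction-error variance per level of
#'   each random term.
#' @return object of class `blup_solution`: `beta` (fixed effects), `u`
#'   (named list of level-named prediction vectors), `fitted`, `residuals`,
#'   `sigma2`, and optionally `pev`.
#' @export
solve_blup <- function(model, vc, pev = FALSE) {
  .check(inherits(model, "mme_model"), "model must come from mme_model()")
  sigma2 <- if (inherits(vc, "variance_components")) vc$sigma2 else vc
  terms <- .prep_terms(model)
  labs <- vapply(terms, `[[`, "", "label")
  .check(all(c(labs, "e") %in% names(sigma2)),
         "vc must name every random term plus 'e'")
  s2 <- as.numeric(sigma2[labs]); s2e <- as.numeric(sigma2["e"])
  .check(all(s2 > 0) && s2e > 0, "variances must be strictly positive")
  ev <- .reml_eval(model, terms, s2, s2e)
  u <- lapply(seq_along(terms), function(i)
    stats::setNames(ev$u[[i]], terms[[i]]$levels))
  names(u) <- labs
  out <- list(beta = stats::setNames(ev$beta, colnames(model$X)), u = u,
              fitted = model$y - ev$resid, residuals = ev$resid,
              sigma2 = stats::setNames(c(s2, s2e), c(labs, "e")))
  if (pev) {
    out$pev <- lapply(seq_along(terms), function(i)
      stats::setNames(ev$pev[[i]], terms[[i]]$levels))
    names(out$pev) <- labs
  }
  class(out) <- "blup_solution"
  out
}

#' @exportS3Method base::print
print.blup_solution <- function(x, ...) {
  cat("BLUP solution:", length(x$beta), "fixed effects;",
      paste(sprintf("%s (%d)", names(x$u), lengths(x$u)), collapse = ", "),
      "random levels\n")
  invisible(x)
}

#' GBLUP: genomic BLUP on a relationship matrix
#'
#' Fits `y = 1 mu + Z g + e` with `g ~ N(0, K sigma2_g)`, estimating the
#' variance components by REML unless supplied. `K` typically is a genomic
#' relationship matrix from [g_matrix()] (possibly adjusted/blended) whose
#' levels may include unphenotyped animals; their GEBV are predicted through
#' the covariance.
#'
#' @param y named numeric vector of responses (names = animal ids).
#' @param K relationship matrix with id dimnames, or `NULL` when `Kinv`
#'   (e.g. an assembled single-step H inverse) is given.
#' @param Kinv optional inverse relationship matrix (sparse or dense).
#' @param vc optional fixed variance components (named: `g`, `e`).
#' @param X optional fixed-effect design (default intercept).
#' @param pev return PEV per animal.
#' @return `blup_solution` with an extra element `gebv` (named vector over
#'   all levels of the relationship matrix) and `vc`.
#' @export
fit_gblup <- function(y, K = NULL, Kinv = NULL, vc = NULL, X = NULL,
                      pev = FALSE) {
  .check(!is.null(names(y)), "y must be named by animal id")
  .check(xor(is.null(K), is.null(Kinv)), "supply exactly one of K or Kinv")
  tm <- random_term("g", ids = names(y), K = K, Kinv = Kinv)
  model <- mme_model(y, X = X, random = list(tm))
  if (is.null(vc)) vc <- reml(model)
  sol <- solve_blup(model, vc, pev = pev)
  sol$gebv <- sol$u$g
  sol$vc <- if (inherits(vc, "variance_components")) vc else
    structure(list(sigma2 = sol$sigma2), class = "variance_components")
  sol
}

#' Genomic-feature BLUP
#'
#' Two genomic random effects: `f` for the markers in the feature set and
#' `r` for the remaining markers, each with its own VanRaden relationship
#' matrix and variance. The reported genomic value is `f + r`. When the
#' feature set covers the whole panel the model degenerates to GBLUP (the
#' `r` term is removed, not floored).
#'
#' @param y named numeric responses (animal ids).
#' @param feature_markers character marker ids forming the feature set.
#' @param panel `genotype_panel` holding all markers for the animals in the
#'   relationship matrices (may include unphenotyped validation animals).
#' @param vc optional fixed variance components (`f`, `r`, `e`).
#' @param pev return PEV.
#' @return `blup_solution` with elements `gebv` (`f + r`, or `g` in the
#'   degenerate case), `vc`, `feature_markers`.
#' @export
fit_gfblup <- function(y, feature_markers, panel, vc = NULL, pev = FALSE) {
  .check(inherits(panel, "genotype_panel"), "panel must be a genotype_panel")
  all_markers <- colnames(panel$dosage)
  feature_markers <- unique(as.character(feature_markers))
  .check(length(feature_markers) > 0,
         "empty feature set: use fit_gblup() instead")
  .check(all(feature_markers %in% all_markers),
         "feature markers must belong to the panel")
  rest <- setdiff(all_markers, feature_markers)
  if (length(rest) == 0) {
    ## degenerate partition: the feature is the whole panel -> plain GBLUP
    G <- g_matrix(panel)
    sol <- fit_gblup(y, K = G, vc = vc, pev = pev)
    sol$feature_markers <- feature_markers
    return(sol)
  }
  Gf <- g_matrix(subset_panel(panel, markers = feature_markers))
  Gr <- g_matrix(subset_panel(panel, markers = rest))
  model <- mme_model(y, random = list(
    random_term("f", ids = names(y), K = Gf),
    random_term("r", ids = names(y), K = Gr)))
  if (is.null(vc)) vc <- reml(model)
  sol <- solve_blup(model, vc, pev = pev)
  sol$gebv <- sol$u$f + sol$u$r
  sol$vc <- if (inherits(vc, "variance_components")) vc else
    structure(list(sigma2 = sol$sigma2), class = "variance_components")
  sol$feature_markers <- feature_markers
  sol
}
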