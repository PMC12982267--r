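# Penalized weighted IRLS for the binomial (logit) additive model.
# Maximises sum_i w_i [y_i log mu_i + (1-y_i) log(1-mu_i)] - 0.5 b' S b
# (up to the factor 2 in the deviance) with step-halving so the penalized
# deviance never increases.
fit_pirls <- function(X, y, w, Smat, beta0 = NULL, max_iter = 60,
                      tol = 1e-9) {
  p <- ncol(X)
  beta <- if (is.null(beta0)) c(stats::qlogis(max(min(
    sum(w * y) / sum(w), 1 - 1e-6), 1e-6)), rep(0, p - 1)) else beta0
  pen_dev <- function(b) {
    eta <- drop(X %*% b)
    binomial_deviance(y, stats::plogis(eta), w) + drop(t(b) %*% Smat %*% b)
  }
  pd <- pen_dev(beta)
  conv <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    v <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / v
    W <- w * v
    XtWX <- crossprod(X, X * W)
    rhs <- crossprod(X, W * z)
    prop <- tryCatch(
      drop(solve(XtWX + Smat + diag(1e-8, p), rhs)),
      error = function(e) stop("IRLS normal equations are singular: ",
                               conditionMessage(e)))
    step <- 1
    repeat {
      cand <- beta + step * (prop - beta)
      pd_new <- pen_dev(cand)
      if (is.finite(pd_new) && pd_new <= pd + 1e-12) break
      step <- step / 2
      if (step < 1e-4) { cand <- beta; pd_new <- pd; break }
    }
    done <- abs(pd - pd_new) < tol * (abs(pd) + 1)
    beta <- cand; pd <- pd_new
    if (done) { conv <- TRUE; break }
  }
  if (max(abs(beta)) > 1e4)
    stop("fit diverged (possible complete separation)")
  list(beta = beta, penalized_deviance = pd, converged = conv, iter = it)
}

#' Weighted binomial deviance
#'
#' @param y 0/1 response.
#' @param mu fitted probabilities.
#' @param w case weights.
#' @return the deviance `-2 sum w [y log mu + (1-y) log(1-mu)]`.
#' @export
binomial_deviance <- function(y, mu, w = rep(1, length(y))) {
  mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  -2 * sum(w * (y * log(mu) + (1 - y) * log(1 - mu)))
}

# Assemble the design matrix and block penalty structure for a term list.
build_design <- function(frame, terms, spatial) {
  blocks <- list()
  X <- matrix(1, nrow(frame), 1)
  colnames(X) <- "(Intercept)"
  at <- 2L
  for (tm in terms) {
    B <- eval_smooth(tm, frame[[tm$name]])
    blocks[[tm$name]] <- list(cols = at:(at + tm$K - 1L), S = tm$S, U = tm$U,
                              spatial = FALSE)
    X <- cbind(X, B)
    at <- at + tm$K
  }
  if (!is.null(spatial)) {
    B <- eval_spatial(spatial, frame$x, frame$y)
    blocks[["xy"]] <- list(cols = at:(at + spatial$K - 1L), S = spatial$S,
                           U = spatial$U, spatial = TRUE)
    X <- cbind(X, B)
  }
  list(X = X, blocks = blocks)
}

assemble_penalty <- function(blocks, p, lambdas, lambda_stars) {
  S <- matrix(0, p, p)
  for (nm in names(blocks)) {
    b <- blocks[[nm]]
    S[b$cols, b$cols] <- lambdas[[nm]] * b$S + lambda_stars[[nm]] * b$U
  }
  S
}

#' Fit a per-species penalized additive suitability model
#'
#' Fits a binomial (logit) additive model with cubic-spline smooths capped
#' at `df_max` effective degrees of freedom per predictor, a low-rank
#' Gaussian radial-basis spatial smooth over (x, y), case weights balancing
#' presences against background, and double-penalty shrinkage so weak terms
#' are removed by the data. Smoothing parameters are chosen by coordinate
#' descent on `lambda_grid`, scoring each candidate by the unpenalized
#' weighted deviance on an internal 75/25 hold-out split (a deliberately
#' simple stand-in for REML; the validation surface here is parameter
#' recovery, not coefficient-level agreement with any other fitter). The
#' final coefficients come from a refit on all rows at the selected
#' smoothing parameters.
#'
#' @param frame model frame from [assemble_model_frame()] (`response`,
#'   `weight`, `x`, `y` + predictor columns).
#' @param predictors character vector of predictor columns to smooth
#'   (default: every column except response/weight/x/y).
#' @param df_max maximum effective df per univariate smooth (default 4).
#' @param spatial_rank rank of the spatial basis (default 30; 0 disables).
#' @param lambda_grid candidate smoothing parameters (shared grid for the
#'   wiggliness and shrinkage penalties).
#' @param select run the smoothing-parameter search? If FALSE all lambdas
#'   are 1.
#' @param sweeps coordinate-descent sweeps over terms (default 2).
#' @param seed integer seed (internal split, k-means centres).
#' @param constants optional standardisation constants (stored for
#'   prediction-time checks).
#' @param species species label carried in the model.
#' @return object of class `SuitabilityModel`.
#' @export
fit_model <- function(frame, predictors = NULL, df_max = 4, spatial_rank = 30,
                      lambda_grid = 10^seq(-3, 6, by = 1.5), select = TRUE,
                      sweeps = 2, seed = 1L, constants = NULL,
                      species = "species", fixed = NULL) {
  if (is.null(predictors))
    predictors <- setdiff(names(frame), c("response", "weight", "x", "y"))
  y <- frame$response
  w <- frame$weight
  if (length(unique(y)) < 2) stop("response has a single class")

  terms <- lapply(predictors, function(nm)
    build_smooth(frame[[nm]], df_max = df_max, name = nm))
  names(terms) <- predictors
  spatial <- if (spatial_rank > 0)
    build_spatial_term(frame$x, frame$y, rank = spatial_rank, seed = seed)
  else NULL

  des <- build_design(frame, terms, spatial)
  X <- des$X; blocks <- des$blocks
  p <- ncol(X)
  bn <- names(blocks)
  lambdas <- stats::setNames(as.list(rep(1, length(bn))), bn)
  lambda_stars <- stats::setNames(as.list(rep(1, length(bn))), bn)
  if (!is.null(spatial)) lambda_stars[["xy"]] <- 0
  if (!is.null(fixed)) {
    # refit at externally chosen smoothing parameters (e.g. per CV fold)
    lambdas[names(fixed$lambdas)] <- fixed$lambdas
    lambda_stars[names(fixed$lambda_stars)] <- fixed$lambda_stars
    select <- FALSE
  }

  if (select) {
    set.seed(split_seed(seed, 23))
    pres <- which(y == 1); bg <- which(y == 0)
    tr <- c(sample(pres, max(1, floor(0.75 * length(pres)))),
            sample(bg, max(1, floor(0.75 * length(bg)))))
    va <- setdiff(seq_along(y), tr)
    Xt <- X[tr, , drop = FALSE]; Xv <- X[va, , drop = FALSE]
    # candidate score: held-out deviance plus a BIC-weighted effective-df
    # penalty, so that under pure noise the flat deviance profile resolves
    # toward shrinkage while real structure (deviance gains far exceeding
    # log(n) per df) keeps its wiggle room
    kappa <- log(length(tr))
    val_dev <- function(lam, lam_s, warm) {
      S <- assemble_penalty(blocks, p, lam, lam_s)
      f <- fit_pirls(Xt, y[tr], w[tr], S, beta0 = warm, max_iter = 40)
      mu_t <- stats::plogis(drop(Xt %*% f$beta))
      Wt <- w[tr] * pmax(mu_t * (1 - mu_t), 1e-10)
      XtWXt <- crossprod(Xt, Xt * Wt)
      edf <- sum(diag(solve(XtWXt + S + diag(1e-8, p), XtWXt)))
      list(dev = binomial_deviance(y[va], stats::plogis(drop(Xv %*% f$beta)),
                                   w[va]) + kappa * edf,
           beta = f$beta)
    }
    # among candidates, take the strongest smoothing whose validation
    # deviance is within `slack` of the minimum (a one-SE-style rule: under
    # pure noise the flat deviance profile then resolves toward shrinkage,
    # while real signal — with deviance costs far exceeding the slack —
    # keeps its wiggle room)
    slack <- 2
    warm <- NULL
    for (sw in seq_len(sweeps)) {
      for (nm in bn) {
        try_grid <- function(cands, setter) {
          devs <- numeric(length(cands))
          for (ci in seq_along(cands)) {
            r <- val_dev(setter(cands[ci])$lam, setter(cands[ci])$lam_s, warm)
            devs[ci] <- r$dev
            warm <<- r$beta
          }
          cands[max(which(devs <= min(devs) + slack))]
        }
        lambdas[[nm]] <- try_grid(
          sort(lambda_grid),
          function(l) { lam <- lambdas; lam[[nm]] <- l
                        list(lam = lam, lam_s = lambda_stars) })
        if (blocks[[nm]]$spatial) next
        lambda_stars[[nm]] <- try_grid(
          sort(c(0, lambda_grid)),
          function(l) { lam_s <- lambda_stars; lam_s[[nm]] <- l
                        list(lam = lambdas, lam_s = lam_s) })
      }
    }
  }

  Sfull <- assemble_penalty(blocks, p, lambdas, lambda_stars)
  fit <- fit_pirls(X, y, w, Sfull)
  eta <- drop(X %*% fit$beta)
  mu <- stats::plogis(eta)
  W <- w * pmax(mu * (1 - mu), 1e-10)
  XtWX <- crossprod(X, X * W)
  H <- solve(XtWX + Sfull + diag(1e-8, p), XtWX)
  edf_all <- diag(H)
  edf <- vapply(bn, function(nm) sum(edf_all[blocks[[nm]]$cols]), numeric(1))
  Vb <- solve(XtWX + Sfull + diag(1e-8, p))

  for (nm in predictors) {
    terms[[nm]]$lambda <- lambdas[[nm]]
    terms[[nm]]$lambda_star <- lambda_stars[[nm]]
  }
  if (!is.null(spatial)) spatial$lambda <- lambdas[["xy"]]

  structure(
    list(species = species, terms = terms, spatial = spatial,
         beta = fit$beta, blocks = blocks,
         lambdas = lambdas, lambda_stars = lambda_stars,
         edf = edf, shrunk_out = names(edf)[edf < 0.1],
         deviance = binomial_deviance(y, mu, w),
         null_deviance = binomial_deviance(y, rep(sum(w * y) / sum(w),
                                                  length(y)), w),
         Vb = Vb, converged = fit$converged, iterations = fit$iter,
         constants = constants, n = length(y)),
    class = "SuitabilityModel")
}

#' @export
print.SuitabilityModel <- function(x, ...) {
  cat(sprintf("SuitabilityModel '%s': n = %d, deviance %.1f (null %.1f)\n",
              x$species, x$n, x$deviance, x$null_deviance))
  cat("  effective df per term:\n")
  for (nm in names(x$edf))
    cat(sprintf("    %-12s %6.2f  (lambda %.3g, lambda* %.3g)%s\n", nm,
                x$edf[[nm]], x$lambdas[[nm]],
                if (nm %in% names(x$lambda_stars)) x$lambda_stars[[nm]] else 0,
                if (nm %in% x$shrunk_out) "  [shrunk out]" else ""))
  invisible(x)
}

#' Linear predictor and probability for new data
#'
#' @param object a `SuitabilityModel`.
#' @param newdata data.frame with the model's predictor columns plus `x`, `y`.
#' @param type `"link"` or `"response"`.
#' @param ... unused.
#' @export
predict.SuitabilityModel <- function(object, newdata,
                                     type = c("response", "link"), ...) {
  type <- match.arg(type)
  miss <- setdiff(names(object$terms), names(newdata))
  if (length(miss))
    stop("newdata is missing predictor columns: ", paste(miss, collapse = ", "))
  eta <- rep(unname(object$beta[1]), nrow(newdata))
  for (tm in object$terms) {
    B <- eval_smooth(tm, newdata[[tm$name]])
    eta <- eta + drop(B %*% object$beta[object$blocks[[tm$name]]$cols])
  }
  if (!is.null(object$spatial)) {
    B <- eval_spatial(object$spatial, newdata$x, newdata$y)
    eta <- eta + drop(B %*% object$beta[object$blocks[["xy"]]$cols])
  }
  if (type == "link") eta else stats::plogis(eta)
}

#' Predict the suitability map over a predictor stack
#'
#' Evaluates the fitted model at every cell centre of the (standardised)
#' predictor stack, including the spatial term.
#'
#' @param model a `SuitabilityModel`.
#' @param stack a standardised `PredictorStack` with the model's layers.
#' @return `RasterGrid` of probabilities in \[0, 1\]; nodata propagated.
#' @export
predict_map <- function(model, stack) {
  miss <- setdiff(names(model$terms), names(stack$layers))
  if (length(miss))
    stop("stack is missing layers: ", paste(miss, collapse = ", "))
  if (!is.null(model$constants) && !is.null(stack$constants)) {
    m <- merge(model$constants, stack$constants, by = "layer")
    if (nrow(m) && any(abs(m$mean.x - m$mean.y) > 1e-9 |
                       abs(m$sd.x - m$sd.y) > 1e-9))
      stop("stack standardisation constants differ from the model's")
  }
  tpl <- stack$layers[[1]]
  cc <- cell_centres(tpl)
  nd <- data.frame(x = cc$x, y = cc$y)
  for (nm in names(model$terms)) nd[[nm]] <- as.vector(stack$layers[[nm]]$values)
  ok <- stats::complete.cases(nd)
  pr <- rep(NA_real_, nrow(nd))
  pr[ok] <- predict(model, nd[ok, , drop = FALSE], type = "response")
  raster_grid(matrix(pr, grid_nrow(tpl), grid_ncol(tpl)),
              tpl$xmin, tpl$ymin, tpl$res)
}

#' Combine per-species suitability maps
#'
#' Sums aligned per-species maps cell-wise and min-max rescales the sum to
#' \[0, 1\] over valid cells; reports the Pearson correlation of the combined
#' map with each input as a check that species-specific structure is
#' retained.
#'
#' @param maps named list of >= 2 aligned `RasterGrid`s.
#' @return list with `combined` (`RasterGrid` in \[0, 1\]) and `correlations`
#'   (named numeric).
#' @export
combine_maps <- function(maps) {
  if (length(maps) < 2) stop("need at least 2 maps to combine")
  do.call(stop_unless_aligned, c(unname(maps), list(what = "suitability maps")))
  tot <- maps[[1]]$values
  for (m in maps[-1]) tot <- tot + m$values
  tpl <- maps[[1]]
  combined <- rescale01(raster_grid(tot, tpl$xmin, tpl$ymin, tpl$res))
  ok <- is.finite(tot)
  cors <- vapply(maps, function(m) {
    if (stats::sd(m$values[ok]) == 0) return(NA_real_)  # constant input
    stats::cor(combined$values[ok], m$values[ok])
  }, numeric(1))
  list(combined = combined, correlations = cors)
}

#' Serialise a fitted model to JSON
#'
#' Writes every reproducibility-relevant component (knots, centres,
#' coefficients, smoothing parameters, standardisation constants) to a JSON
#' file; [read_model()] restores a model whose predictions are identical.
#'
#' @param model a `SuitabilityModel`.
#' @param path output path.
#' @export
write_model <- function(model, path) {
  ser <- list(
    species = model$species,
    beta = model$beta,
    lambdas = model$lambdas,
    lambda_stars = model$lambda_stars,
    edf = as.list(model$edf),
    terms = lapply(model$terms, function(tm)
      list(name = tm$name, knots = tm$knots, lo = tm$lo, hi = tm$hi,
           K = tm$K, colmeans = tm$colmeans,
           lambda = tm$lambda, lambda_star = tm$lambda_star)),
    spatial = if (!is.null(model$spatial))
      list(centres = unname(apply(model$spatial$centres, 1, c, simplify = FALSE)),
           sigma = model$spatial$sigma, K = model$spatial$K,
           colmeans = model$spatial$colmeans, lambda = model$spatial$lambda),
    blocks = lapply(model$blocks, function(b) list(cols = b$cols)),
    constants = model$constants
  )
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Restore a model written by [write_model()]
#'
#' @param path JSON file path.
#' @return a `SuitabilityModel` (prediction-capable; fitting diagnostics such
#'   as `Vb` are not serialised).
#' @export
read_model <- function(path) {
  s <- jsonlite::read_json(path, simplifyVector = TRUE)
  terms <- lapply(s$terms, function(tm) {
    t2 <- structure(
      list(name = tm$name, knots = tm$knots, lo = tm$lo, hi = tm$hi,
           K = tm$K, S = crossprod(diff(diag(tm$K), differences = 2)),
           U = NULL, colmeans = tm$colmeans,
           lambda = tm$lambda, lambda_star = tm$lambda_star),
      class = "SmoothTerm")
    t2
  })
  names(terms) <- vapply(terms, `[[`, character(1), "name")
  spatial <- NULL
  if (!is.null(s$spatial) && length(s$spatial)) {
    centres <- s$spatial$centres
    if (!is.matrix(centres))
      centres <- do.call(rbind, lapply(centres, unlist))
    spatial <- structure(
      list(centres = centres, sigma = s$spatial$sigma, K = s$spatial$K,
           S = diag(s$spatial$K), U = matrix(0, s$spatial$K, s$spatial$K),
           colmeans = s$spatial$colmeans, lambda = s$spatial$lambda,
           lambda_star = 0),
      class = "SpatialTerm")
  }
  structure(
    list(species = s$species, terms = terms, spatial = spatial,
         beta = s$beta, blocks = lapply(s$blocks, function(b)
           list(cols = b$cols)),
         lambdas = s$lambdas, lambda_stars = s$lambda_stars,
         edf = unlist(s$edf), constants = s$constants),
    class = "SuitabilityModel")
}
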