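#' Filter occurrence records
#'
#' Applies the record-cleaning rules in a fixed order, counting each removal
#' under exactly one reason: (1) records dated outside `[year_min, year_max]`
#' (missing years pass to stage 3), (2) coordinate uncertainty above
#' `max_uncertainty_m` — missing uncertainty fails this rule, conservatively —
#' (3) undated records, (4) duplicates on (species, x, y, year), keeping the
#' first occurrence. Filtering is idempotent.
#'
#' @param records data.frame with columns `species`, `x`, `y`, `year`,
#'   `uncertainty_m` (further columns are carried through).
#' @param year_min,year_max inclusive year window (defaults 2015-2022).
#' @param max_uncertainty_m maximum coordinate uncertainty (m), default 100.
#' @return list with `records` (the retained rows) and `audit`
#'   (class `FilterAudit`: n_input, n_removed_year, n_removed_uncertainty,
#'   n_removed_undated, n_removed_duplicate, n_output).
#' @export
filter_records <- function(records, year_min = 2015, year_max = 2022,
                           max_uncertainty_m = 100) {
  need <- c("species", "x", "y", "year", "uncertainty_m")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records are missing required columns: ", paste(miss, collapse = ", "))
  n_input <- nrow(records)
  if (n_input == 0) {
    warning("empty record table")
    audit <- filter_audit(0, 0, 0, 0, 0)
    return(list(records = records, audit = audit))
  }
  stopifnot(all(is.finite(records$x)), all(is.finite(records$y)))

  in_year <- is.na(records$year) |
    (records$year >= year_min & records$year <= year_max)
  n_year <- sum(!in_year)
  r <- records[in_year, , drop = FALSE]

  ok_unc <- !is.na(r$uncertainty_m) & r$uncertainty_m <= max_uncertainty_m
  n_unc <- sum(!ok_unc)
  r <- r[ok_unc, , drop = FALSE]

  dated <- !is.na(r$year)
  n_und <- sum(!dated)
  r <- r[dated, , drop = FALSE]

  dup <- duplicated(r[, c("species", "x", "y", "year")])
  n_dup <- sum(dup)
  r <- r[!dup, , drop = FALSE]
  rownames(r) <- NULL

  list(records = r,
       audit = filter_audit(n_input, n_year, n_unc, n_und, n_dup))
}

filter_audit <- function(n_input, n_year, n_unc, n_und, n_dup) {
  a <- list(n_input = n_input,
            n_removed_year = n_year,
            n_removed_uncertainty = n_unc,
            n_removed_undated = n_und,
            n_removed_duplicate = n_dup,
            n_output = n_input - n_year - n_unc - n_und - n_dup)
  stopifnot(all(unlist(a) >= 0))
  structure(a, class = "FilterAudit")
}

#' @export
print.FilterAudit <- function(x, ...) {
  cat(sprintf(
    "FilterAudit: %d in -> %d out (removed: %d out-of-year, %d uncertain, %d undated, %d duplicate)\n",
    x$n_input, x$n_output, x$n_removed_year, x$n_removed_uncertainty,
    x$n_removed_undated, x$n_removed_duplicate))
  invisible(x)
}

#' KDE-weighted background (pseudo-absence) points
#'
#' Draws, per species, `multiplier` times the number of presences as
#' background points over the valid cells of the analysis grid, with
#' selection probability proportional to a Gaussian kernel density estimate
#' of that species' presences evaluated at cell centres — so background
#' sampling mirrors the spatial recording effort implied by the presences.
#' Cells are sampled with replacement by default (several background points
#' may share a cell), which keeps the empirical background density
#' proportional to the KDE; `replace = FALSE` draws distinct cells instead
#' when enough valid cells exist (falling back to replacement otherwise,
#' flagged via the `with_replacement` attribute).
#'
#' @param presences data.frame with `species`, `x`, `y` (>= 2 rows/species).
#' @param grid analysis `RasterGrid` (values define nodata; any finite value
#'   is a valid cell).
#' @param multiplier background points per presence (default 10).
#' @param bandwidth_m kernel bandwidth; default Silverman's rule per axis on
#'   each species' presence coordinates.
#' @param seed integer seed.
#' @param replace sample cells with replacement (default TRUE)?
#' @return data.frame `species`, `x`, `y`, `is_presence = FALSE` with one
#'   block per species.
#' @export
kde_background <- function(presences, grid, multiplier = 10,
                           bandwidth_m = NULL, seed = 1L, replace = TRUE) {
  valid <- which(is.finite(as.vector(grid$values)))
  if (!length(valid)) stop("grid has no valid cells")
  cc <- cell_centres(grid)
  out <- list()
  for (sp in unique(presences$species)) {
    p <- presences[presences$species == sp, , drop = FALSE]
    if (nrow(p) < 2)
      stop(sprintf("species '%s' has fewer than 2 presences", sp))
    h <- bandwidth_m
    if (is.null(h)) {
      silverman <- function(v) {
        s <- stats::sd(v)
        1.06 * max(s, 1e-6) * length(v)^(-1/5)
      }
      h <- c(silverman(p$x), silverman(p$y))
    }
    if (length(h) == 1) h <- c(h, h)
    dens <- rep(0, length(valid))
    for (i in seq_len(nrow(p)))
      dens <- dens + exp(-0.5 * (((cc$x[valid] - p$x[i]) / h[1])^2 +
                                 ((cc$y[valid] - p$y[i]) / h[2])^2))
    n_bg <- multiplier * nrow(p)
    set.seed(split_seed(seed, 400 + match(sp, unique(presences$species))))
    repl <- replace || n_bg > length(valid)
    pick <- sample(seq_along(valid), n_bg, replace = repl, prob = dens)
    cells <- valid[pick]
    bg <- data.frame(species = sp, x = cc$x[cells], y = cc$y[cells],
                     is_presence = FALSE)
    attr(bg, "with_replacement") <- repl
    out[[sp]] <- bg
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "with_replacement") <-
    any(vapply(out, attr, logical(1), which = "with_replacement"))
  res
}

#' Assemble the model frame for one species
#'
#' Combines presences and background points, extracts predictor values at
#' the analysis cell containing each point, and sets case weights so the
#' total presence weight equals the total background weight (presence weight
#' `n_bg / n_pres`, background weight 1, then rescaled to mean 1) — the
#' equal-class weighting used to offset the deliberate 10:1 background
#' imbalance. Points outside the predictor extent (or on nodata cells) are
#' dropped and counted.
#'
#' @param presences data.frame with `x`, `y` (single species).
#' @param background data.frame with `x`, `y` (single species).
#' @param stack standardised `PredictorStack`.
#' @return data.frame with `response` (1/0), `weight`, `x`, `y` and one
#'   column per stack layer; attribute `n_dropped_outside` counts dropped
#'   points.
#' @export
assemble_model_frame <- function(presences, background, stack) {
  pts <- rbind(
    data.frame(x = presences$x, y = presences$y, response = 1),
    data.frame(x = background$x, y = background$y, response = 0)
  )
  vals <- extract_stack(stack, pts$x, pts$y)
  inside <- stats::complete.cases(vals)
  n_drop <- sum(!inside)
  if (n_drop > 0)
    warning(sprintf("%d points outside the predictor extent were dropped", n_drop))
  pts <- pts[inside, , drop = FALSE]
  vals <- vals[inside, , drop = FALSE]
  n_pres <- sum(pts$response == 1)
  n_bg <- sum(pts$response == 0)
  if (n_pres == 0 || n_bg == 0)
    stop("model frame needs both presences and background points inside the extent")
  w <- ifelse(pts$response == 1, n_bg / n_pres, 1)
  w <- w / mean(w)
  frame <- cbind(data.frame(response = pts$response, weight = w,
                            x = pts$x, y = pts$y), vals)
  rownames(frame) <- NULL
  attr(frame, "n_dropped_outside") <- n_drop
  frame
}
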