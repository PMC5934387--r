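# Hartemink mutual-information preserving discretization.
#
# Each variable is z-scored and quantile-binned into `ibreaks` initial
# levels; adjacent levels are then merged greedily -- cycling over the
# variables in a fixed order -- choosing at each step the merge that loses
# the least total pairwise mutual information with the other variables,
# until every variable has `levels` levels. The final cut points (on the
# z-scored scale) are recorded so the same mapping can be replayed on new
# data.

# empirical mutual information (nats) between two integer-coded vectors
#' @noRd
.mutual_information <- function(a, ra, b, rb) {
  n <- length(a)
  joint <- tabulate(a + ra * (b - 1L), nbins = ra * rb) / n
  pa <- tabulate(a, nbins = ra) / n
  pb <- tabulate(b, nbins = rb) / n
  pij <- matrix(joint, nrow = ra)
  pos <- pij > 0
  sum(pij[pos] * log(pij[pos] / (pa[row(pij)[pos]] * pb[col(pij)[pos]])))
}

# initial binning of a z-scored vector: if there are at most `ibreaks`
# distinct values each value gets its own level (cuts at midpoints),
# otherwise quantile bins (duplicated quantiles collapsed). Intervals are
# left-closed: level = findInterval(z, cuts) + 1.
#' @noRd
.initial_bins <- function(z, ibreaks) {
  uq <- sort(unique(z))
  if (length(uq) <= ibreaks) {
    cuts <- if (length(uq) > 1)
      (uq[-length(uq)] + uq[-1]) / 2 else numeric(0)
  } else {
    q <- stats::quantile(z, probs = seq(0, 1, length.out = ibreaks + 1),
                         names = FALSE)
    cuts <- sort(unique(q[-c(1, ibreaks + 1)]))
    cuts <- cuts[cuts > min(z) & cuts <= max(z)]
  }
  list(code = findInterval(z, cuts) + 1L, cuts = cuts)
}

#' Hartemink mutual-information discretization
#'
#' Discretizes each column of an eigengene matrix into `levels` ordered
#' levels (default 3) by quantile binning into `ibreaks` initial levels
#' followed by greedy merging of adjacent levels so as to preserve the total
#' pairwise mutual information between the variables (Hartemink's method).
#' Because the initial binning is rank-based, the discretization is invariant
#' to strictly monotone transforms of the inputs. A constant variable maps to
#' the middle level with a warning. With a single variable (no pairwise
#' information to preserve) the variable is quantile-binned directly into
#' `levels` levels.
#'
#' @param e samples x variables numeric matrix.
#' @param levels target number of levels per variable.
#' @param ibreaks number of initial quantile bins (lowered per variable to
#'   the number of distinct values when smaller).
#' @return list with `model` (a `discretization_model`: per-variable cut
#'   points on the z-scored scale) and `discrete` (integer matrix of codes
#'   1..levels).
#' @export
hartemink_discretize <- function(e, levels = 3L, ibreaks = 20L) {
  if (!is.matrix(e)) e <- as.matrix(e)
  if (is.null(colnames(e))) colnames(e) <- paste0("V", seq_len(ncol(e)))
  vars <- colnames(e)
  p <- length(vars)
  n <- nrow(e)
  levels <- as.integer(levels)
  stopifnot(levels >= 2L, n >= levels)

  zmat <- matrix(0, n, p, dimnames = dimnames(e))
  constant <- logical(p)
  for (j in seq_len(p)) {
    sdj <- stats::sd(e[, j])
    if (sdj == 0) {
      constant[j] <- TRUE
      warning("variable ", vars[j], " is constant; mapped to the middle level")
    } else zmat[, j] <- (e[, j] - mean(e[, j])) / sdj
  }

  active <- which(!constant)
  code <- matrix(1L, n, p, dimnames = dimnames(e))
  all_cuts <- vector("list", p)
  names(all_cuts) <- vars
  nlev <- integer(p)

  if (length(active) == 1L) {
    # no pairwise information to preserve: direct quantile binning
    j <- active
    q <- stats::quantile(zmat[, j], probs = seq_len(levels - 1) / levels,
                         names = FALSE)
    cuts <- sort(unique(q))
    code[, j] <- findInterval(zmat[, j], cuts) + 1L
    all_cuts[[j]] <- cuts
    nlev[j] <- length(cuts) + 1L
  } else if (length(active) > 1L) {
    for (j in active) {
      b <- .initial_bins(zmat[, j], ibreaks)
      code[, j] <- b$code
      all_cuts[[j]] <- b$cuts
      nlev[j] <- length(b$cuts) + 1L
    }
    # greedy merging, cycling over variables in column order
    while (any(nlev[active] > levels)) {
      for (j in active) {
        if (nlev[j] <= levels) next
        others <- setdiff(active, j)
        best_loss <- Inf
        best_code <- NULL
        best_l <- NA_integer_
        base_mi <- sum(vapply(others, function(u)
          .mutual_information(code[, j], nlev[j], code[, u], nlev[u]),
          numeric(1)))
        for (l in seq_len(nlev[j] - 1L)) {
          cand <- code[, j]
          cand[cand > l] <- cand[cand > l] - 1L
          mi <- sum(vapply(others, function(u)
            .mutual_information(cand, nlev[j] - 1L, code[, u], nlev[u]),
            numeric(1)))
          loss <- base_mi - mi
          if (loss < best_loss - 1e-12) {
            best_loss <- loss
            best_code <- cand
            best_l <- l
          }
        }
        code[, j] <- best_code
        all_cuts[[j]] <- all_cuts[[j]][-best_l]
        nlev[j] <- nlev[j] - 1L
      }
    }
  }

  for (j in which(constant)) {
    code[, j] <- as.integer(ceiling(levels / 2))
    nlev[j] <- 1L
  }

  model <- structure(list(cuts = all_cuts, levels = levels,
                          ibreaks = as.integer(ibreaks), vars = vars),
                     class = "discretization_model")
  list(model = model, discrete = code)
}

#' Replay a learned discretization on new data
#'
#' New variables are z-scored within the new dataset and the stored cut
#' points are applied. Together with the within-dataset standardization used
#' by [project_eigengenes()], this makes the discrete codes invariant to
#' per-gene affine transforms of the new platform. A constant new variable
#' maps to the middle level.
#'
#' @param model a `discretization_model`.
#' @param e samples x variables matrix with the model's variables.
#' @return integer matrix of discrete codes.
#' @export
apply_discretization <- function(model, e) {
  if (!is.matrix(e)) e <- as.matrix(e)
  missing_vars <- setdiff(model$vars, colnames(e))
  if (length(missing_vars) > 0)
    stop("missing variables: ", paste(missing_vars, collapse = ", "))
  out <- matrix(1L, nrow(e), length(model$vars),
                dimnames = list(rownames(e), model$vars))
  mid <- as.integer(ceiling(model$levels / 2))
  for (j in seq_along(model$vars)) {
    v <- model$vars[j]
    cuts <- model$cuts[[v]]
    if (is.null(cuts)) {
      out[, j] <- mid
      next
    }
    x <- e[, v]
    sdx <- stats::sd(x)
    if (sdx == 0) {
      out[, j] <- mid
      next
    }
    z <- (x - mean(x)) / sdx
    out[, j] <- findInterval(z, cuts) + 1L
  }
  out
}
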