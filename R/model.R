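# Bivariate cubic IC50 model: ic50 = sum_k alpha_k * phi_k(D, zeta) with the
# fixed feature order phi = [1, D, z, D^2, Dz, z^2, D^2 z, D z^2, z^3].

.feature_names <- c("1", "D", "zeta", "D2", "Dzeta", "zeta2",
                    "D2zeta", "Dzeta2", "zeta3")

#' Feature vector of the bivariate cubic IC50 model
#'
#' Returns the nine monomials `[1, D, z, D^2, Dz, z^2, D^2 z, D z^2, z^3]`
#' in this exact order (the order the model coefficients pair with).
#' The `D^3` monomial is deliberately absent from the model family.
#'
#' @param D,zeta external and internal activity (finite reals; vectors of
#'   equal length allowed).
#' @return for scalar input a length-9 named numeric vector; for vector
#'   input a matrix with one row per `(D, zeta)` pair.
#' @export
feature_vector <- function(D, zeta) {
  if (!all(is.finite(D)) || !all(is.finite(zeta))) {
    stop_molactivity("domain_error", "D and zeta must be finite")
  }
  m <- cbind(1, D, zeta, D^2, D * zeta, zeta^2, D^2 * zeta, D * zeta^2, zeta^3)
  colnames(m) <- .feature_names
  if (length(D) == 1L) m[1L, ] else m
}

#' Reference model coefficients
#'
#' The nine coefficients of the anti-tyrosinase IC50 model as published,
#' rounded to 4 significant figures. These equal the exact interpolating
#' solution of [fit_ic50()] on the bundled nine-flavonoid training table,
#' rounded; because the model is severely ill-conditioned, this rounding
#' moves predictions materially (see the methods vignette), so screening
#' should normally use the refit coefficients.
#'
#' @return an `ic50_model` with provenance `"printed"` and no diagnostics.
#' @export
printed_model <- function() {
  alpha <- c(4.571e5, -9.612e7, 1.027e6, 1.197e9, 8.704e8,
             -4.565e7, -7.457e9, -1.715e9, 1.363e8)
  new_ic50_model(alpha, provenance = "printed")
}

new_ic50_model <- function(coefficients, provenance = c("printed", "refit", "custom"),
                           diagnostics = NULL) {
  provenance <- match.arg(provenance)
  stopifnot(length(coefficients) == 9L, all(is.finite(coefficients)))
  coefficients <- as.numeric(coefficients)
  names(coefficients) <- paste0("alpha", 1:9)
  structure(list(coefficients = coefficients, provenance = provenance,
                 diagnostics = diagnostics),
            class = "ic50_model")
}

#' @export
print.ic50_model <- function(x, ...) {
  cat(sprintf("<ic50_model> provenance: %s\n", x$provenance))
  print(signif(x$coefficients, 10))
  if (!is.null(x$diagnostics)) {
    cat(sprintf("SSE = %.4g, R^2 = %.10f\n",
                x$diagnostics$sse, x$diagnostics$r_squared))
  }
  invisible(x)
}

# --- double-double helpers -------------------------------------------------
# Error-free transforms (Dekker/Knuth). Only what mixed-precision iterative
# refinement of the 9x9 solve needs: an accurate residual b - A x.

.two_sum <- function(a, b) {
  s <- a + b
  bb <- s - a
  err <- (a - (s - bb)) + (b - bb)
  c(s, err)
}

.split_double <- function(a) {
  t <- 134217729 * a  # 2^27 + 1
  hi <- t - (t - a)
  c(hi, a - hi)
}

.two_prod <- function(a, b) {
  p <- a * b
  as_ <- .split_double(a)
  bs <- .split_double(b)
  err <- ((as_[1] * bs[1] - p) + as_[1] * bs[2] + as_[2] * bs[1]) + as_[2] * bs[2]
  c(p, err)
}

# Accurate residual r_i = b_i - sum_j A_ij x_j, accumulated in double-double.
.dd_residual <- function(A, x, b) {
  n <- nrow(A)
  r <- numeric(n)
  for (i in seq_len(n)) {
    hi <- b[i]; lo <- 0
    for (j in seq_len(ncol(A))) {
      p <- .two_prod(-A[i, j], x[j])
      s <- .two_sum(hi, p[1])
      hi <- s[1]
      lo <- lo + s[2] + p[2]
    }
    r[i] <- hi + lo
  }
  r
}

# Square solve with mixed-precision iterative refinement. The design matrix
# has condition number around 1e12 (monomials of D ~ 1e-2 and zeta ~ 2e-1 on
# a narrow descriptor range), so a plain double solve loses ~12 digits;
# refinement against a double-double residual restores the solution to
# working accuracy.
.solve_refined <- function(A, b, iterations = 40L) {
  qrA <- qr(A)
  if (qrA$rank < ncol(A)) {
    stop_molactivity("singular_fit_error",
                     "design matrix is rank deficient")
  }
  x <- qr.solve(qrA, b)
  for (k in seq_len(iterations)) {
    r <- .dd_residual(A, x, b)
    dx <- qr.solve(qrA, r)
    xn <- x + dx
    if (all(xn == x)) break
    x <- xn
  }
  x
}

#' Fit the nine-coefficient IC50 model
#'
#' With exactly nine training records the model interpolates: the square
#' linear system is solved to working precision by QR factorisation with
#' mixed-precision iterative refinement (double-double residuals), which
#' is required because the design matrix's condition number is about
#' 1e12. With more than nine records an ordinary least-squares fit is
#' returned.
#'
#' @param training data frame with columns `name`, `D`, `zeta`, `ic50`
#'   (observed, in uM), e.g. from [load_training_table()].
#' @return an `ic50_model` with provenance `"refit"` and diagnostics
#'   (`sse`, `r_squared`, per-compound `residuals`).
#' @examples
#' m <- fit_ic50(load_training_table())
#' m$diagnostics$r_squared  # 1 to well beyond 9 decimals
#' @export
fit_ic50 <- function(training) {
  stopifnot(is.data.frame(training),
            all(c("D", "zeta", "ic50") %in% names(training)))
  ok <- is.finite(training$ic50)
  training <- training[ok, , drop = FALSE]
  if (nrow(training) < 9L) {
    stop_molactivity("underdetermined_error",
                     sprintf("need at least 9 records with observed IC50, got %d",
                             nrow(training)))
  }
  A <- feature_vector(training$D, training$zeta)
  dup <- duplicated(paste(training$D, training$zeta))
  if (any(dup)) {
    stop_molactivity(
      "singular_fit_error",
      sprintf("duplicate (D, zeta) rows make interpolation impossible: %s",
              paste(training$name[dup], collapse = ", ")))
  }
  alpha <- if (nrow(training) == 9L) {
    tryCatch(.solve_refined(A, training$ic50),
             singular_fit_error = function(e) {
               stop_molactivity("singular_fit_error",
                                "design matrix is rank deficient (collinear descriptor rows)")
             })
  } else {
    qrA <- qr(A)
    if (qrA$rank < 9L) {
      stop_molactivity("singular_fit_error", "design matrix is rank deficient")
    }
    qr.solve(qrA, training$ic50)
  }
  model <- new_ic50_model(alpha, provenance = "refit")
  model$diagnostics <- goodness_of_fit(model, training)
  model
}

#' Predict IC50 from activity indices
#'
#' Dot product of the model coefficients with [feature_vector()].
#' Predictions may be negative: the model is an interpolating polynomial
#' and compounds far outside the training descriptor range extrapolate
#' hard (the screening table interprets relative magnitudes). A warning
#' flags negative predictions as outside the applicability domain; values
#' are reported as-is, never clipped.
#'
#' @param object an `ic50_model`.
#' @param D,zeta activity indices (vectors of equal length allowed).
#' @param quiet suppress the applicability-domain warning.
#' @param ... unused.
#' @return numeric vector of predicted IC50 (uM).
#' @export
predict.ic50_model <- function(object, D, zeta, quiet = FALSE, ...) {
  f <- feature_vector(D, zeta)
  if (is.null(dim(f))) f <- matrix(f, nrow = 1L)
  p <- drop(f %*% object$coefficients)
  if (!quiet && any(p < 0)) {
    warning(sprintf("%d prediction(s) are negative: outside the applicability domain, interpret relative magnitude only",
                    sum(p < 0)), call. = FALSE)
  }
  p
}

#' Goodness of fit of an IC50 model
#'
#' Residuals are `observed - predicted`; `sse` is their sum of squares and
#' `r_squared = 1 - sse / sst` with `sst` the total sum of squares about
#' the mean observed IC50.
#'
#' @param model an `ic50_model`.
#' @param training data frame with `D`, `zeta` and observed `ic50`.
#' @return list with `sse`, `r_squared` and `residuals`.
#' @export
goodness_of_fit <- function(model, training) {
  pred <- predict(model, training$D, training$zeta, quiet = TRUE)
  res <- training$ic50 - pred
  sst <- sum((training$ic50 - mean(training$ic50))^2)
  if (sst == 0) {
    stop_molactivity("undefined_r2_error",
                     "all observed IC50 equal; R^2 undefined")
  }
  sse <- sum(res^2)
  list(sse = sse, r_squared = 1 - sse / sst, residuals = res)
}

#' Rank compounds by predicted potency
#'
#' Sorts ascending by predicted IC50 (strongest inhibitor first); ties are
#' broken by name, lexicographically in the C locale.
#'
#' @param model an `ic50_model`.
#' @param compounds data frame with columns `name`, `D`, `zeta`.
#' @return the input with `ic50_predicted` and `rank` (1..N) added, sorted
#'   by rank. Empty input returns an empty data frame.
#' @export
rank_compounds <- function(model, compounds) {
  if (nrow(compounds) == 0L) {
    compounds$ic50_predicted <- numeric(0)
    compounds$rank <- integer(0)
    return(compounds)
  }
  compounds$ic50_predicted <- predict(model, compounds$D, compounds$zeta,
                                      quiet = TRUE)
  o <- order(compounds$ic50_predicted, compounds$name, method = "radix")
  out <- compounds[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Serialize model coefficients to JSON
#'
#' Writes ordered `alpha1..alpha9` plus the provenance tag.
#'
#' @param model an `ic50_model`.
#' @param path output path.
#' @export
write_coefficients <- function(model, path) {
  obj <- c(as.list(model$coefficients), list(provenance = model$provenance))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read model coefficients from JSON
#'
#' @param path JSON file written by [write_coefficients()] (or hand-made
#'   with keys `alpha1..alpha9`).
#' @return an `ic50_model` with provenance `"custom"` unless the file says
#'   otherwise.
#' @export
read_coefficients <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  alpha <- unlist(obj[paste0("alpha", 1:9)])
  if (length(alpha) != 9L || any(is.na(alpha))) {
    stop_molactivity("invalid_coefficients_error",
                     "expected keys alpha1..alpha9 with numeric values")
  }
  prov <- if (!is.null(obj$provenance) &&
              obj$provenance %in% c("printed", "refit", "custom")) {
    obj$provenance
  } else "custom"
  new_ic50_model(as.numeric(alpha), provenance = prov)
}
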