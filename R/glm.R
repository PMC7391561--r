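# Binomial GLM machinery: deviance-based D-squared and adjusted D-squared,
# single-predictor screens with Bonferroni correction, and three-matrix
# variation partitioning on the adjusted-D2 scale.

#' Fit a binomial GLM and report explained deviance
#'
#' Logit-link maximum-likelihood fit (IRLS via `stats::glm`), augmented
#' with the deviance-based coefficient of determination
#' D2 = (null deviance - residual deviance) / null deviance and its
#' adjusted form
#' adj D2 = 1 - ((n - 1) / (n - p)) * (1 - D2),
#' where p counts all fitted coefficients including the intercept.
#' Complete or quasi-complete separation is flagged (fitted probabilities
#' numerically 0/1 or |coefficient| > 15 on standardized predictors);
#' coefficients then diverge but deviances at the convergence cutoff are
#' still reported.
#'
#' @param y binary 0/1 response vector.
#' @param X numeric predictor matrix or data.frame (no intercept column;
#'   one is added).
#' @param allow_aliased if `TRUE`, perfectly collinear columns are dropped
#'   from the fit (and from the coefficient count) instead of raising an
#'   error; used by [varpart3()], where unions of predictor matrices may
#'   be collinear by construction.
#' @return object of class `refugeo_glm`: list with `coefficients`
#'   (estimate, se, z, p per term), `null_deviance`, `residual_deviance`,
#'   `n`, `p_params`, `d2`, `adj_d2`, `separation`, and the underlying
#'   `fit`.
#' @export
fit_binomial_glm <- function(y, X, allow_aliased = FALSE) {
  X <- as.data.frame(X)
  if (!all(y %in% c(0, 1))) stop("fit_binomial_glm: y must be 0/1")
  if (nrow(X) != length(y))
    stop("fit_binomial_glm: X rows must match length(y)")
  dat <- data.frame(.y = y, X, check.names = FALSE)
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = dat, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-12,
                                            maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w))) {
        sep_warn <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (any(is.na(coef(fit))) && !allow_aliased) {
    aliased <- names(coef(fit))[is.na(coef(fit))]
    stop("fit_binomial_glm: rank-deficient design; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }
  sm <- summary(fit)$coefficients
  co <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                   z = sm[, 3], p = sm[, 4], row.names = NULL)
  n <- length(y)
  p_params <- sum(!is.na(coef(fit)))
  if (n <= p_params)
    stop("fit_binomial_glm: need more observations than coefficients")
  d2 <- (fit$null.deviance - fit$deviance) / fit$null.deviance
  adj_d2 <- 1 - ((n - 1) / (n - p_params)) * (1 - d2)
  separation <- sep_warn ||
    any(abs(coef(fit)[-1]) > 15, na.rm = TRUE)
  if (separation)
    warning("fit_binomial_glm: (quasi-)separation detected; coefficient ",
            "estimates diverge")
  structure(list(coefficients = co, null_deviance = fit$null.deviance,
                 residual_deviance = fit$deviance, n = n,
                 p_params = p_params, d2 = d2, adj_d2 = adj_d2,
                 separation = separation, fit = fit),
            class = "refugeo_glm")
}

#' @export
print.refugeo_glm <- function(x, ...) {
  cat(sprintf("Binomial GLM: n = %d, D2 = %.4f, adjusted D2 = %.4f%s\n",
              x$n, x$d2, x$adj_d2,
              if (x$separation) " [separation flagged]" else ""))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Single-predictor binomial GLM screen with Bonferroni correction
#'
#' Fits one binomial GLM per predictor column against the same binary
#' response and Bonferroni-adjusts the Wald p value of each slope:
#' p_adj = min(1, p * family_size).
#'
#' @param y binary 0/1 response.
#' @param predictors data.frame/matrix of named predictor columns.
#' @param family_size number of tests in the Bonferroni family (defaults
#'   to the number of predictors screened; must be at least that).
#' @param alpha significance level applied to the adjusted p values.
#' @return data.frame with one row per predictor: `predictor`, `estimate`,
#'   `se`, `z`, `p`, `p_adj`, `significant`, `d2`, `adj_d2`, `separation`.
#' @export
single_predictor_screen <- function(y, predictors,
                                    family_size = ncol(predictors),
                                    alpha = 0.05) {
  predictors <- as.data.frame(predictors)
  if (family_size < ncol(predictors))
    stop("single_predictor_screen: family_size smaller than the number ",
         "of predictors screened")
  rows <- lapply(names(predictors), function(nm) {
    f <- fit_binomial_glm(y, predictors[nm])
    sl <- f$coefficients[2, ]
    data.frame(predictor = nm, estimate = sl$estimate, se = sl$se,
               z = sl$z, p = sl$p,
               p_adj = min(1, sl$p * family_size),
               d2 = f$d2, adj_d2 = f$adj_d2, separation = f$separation)
  })
  out <- do.call(rbind, rows)
  out$significant <- out$p_adj < alpha
  out
}

#' Three-matrix variation partitioning on the adjusted-D2 scale
#'
#' Partitions the variation of a binary response explained by three
#' predictor matrices (here: ecology A, colonization history B, apomict
#' occurrence C) into unique, pairwise-joint and three-way-joint
#' fractions, extending the partial-regression logic of `vegan::varpart`
#' to binomial GLMs with adjusted D2 as the explained-variation measure.
#' With R(.) = adjusted D2 of the model on the union of the named
#' matrices:
#' \deqn{a = R(ABC) - R(BC), \quad b = R(ABC) - R(AC), \quad
#'       c = R(ABC) - R(AB)}
#' \deqn{d = R(AC) + R(BC) - R(ABC) - R(C), \quad
#'       e = R(AB) + R(AC) - R(ABC) - R(A), \quad
#'       f = R(AB) + R(BC) - R(ABC) - R(B)}
#' \deqn{g = R(ABC) - a - b - c - d - e - f, \quad
#'       residual = 1 - R(ABC)}
#' Fractions may be negative and are reported unclamped (the vegan
#' convention).
#'
#' @param y binary 0/1 response.
#' @param X_A,X_B,X_C predictor matrices/data.frames sharing the same
#'   rows.
#' @param labels length-3 character vector naming the matrices.
#' @return object of class `varpart3` with `fractions` (a..g, residual),
#'   `adj_d2` of the 7 constituent models, `labels`, `n`.
#' @export
varpart3 <- function(y, X_A, X_B, X_C,
                     labels = c("eco", "hist", "apo")) {
  X_A <- as.data.frame(X_A); X_B <- as.data.frame(X_B)
  X_C <- as.data.frame(X_C)
  if (!all(nrow(X_A) == c(nrow(X_B), nrow(X_C), length(y))))
    stop("varpart3: matrices and response differ in row count")
  if (!ncol(X_A) || !ncol(X_B) || !ncol(X_C))
    stop("varpart3: every predictor matrix must be non-empty")
  # block prefixes keep column names unique across matrix unions
  names(X_A) <- paste0("A.", names(X_A))
  names(X_B) <- paste0("B.", names(X_B))
  names(X_C) <- paste0("C.", names(X_C))
  fitR <- function(X, which) {
    tryCatch(suppressWarnings(fit_binomial_glm(y, X,
                                               allow_aliased = TRUE))$adj_d2,
             error = function(e)
               stop("varpart3: model '", which, "' failed: ",
                    conditionMessage(e), call. = FALSE))
  }
  R <- c(A   = fitR(X_A, "A"),
         B   = fitR(X_B, "B"),
         C   = fitR(X_C, "C"),
         AB  = fitR(cbind(X_A, X_B), "AB"),
         AC  = fitR(cbind(X_A, X_C), "AC"),
         BC  = fitR(cbind(X_B, X_C), "BC"),
         ABC = fitR(cbind(X_A, X_B, X_C), "ABC"))
  a <- R[["ABC"]] - R[["BC"]]
  b <- R[["ABC"]] - R[["AC"]]
  cc <- R[["ABC"]] - R[["AB"]]
  d <- R[["AC"]] + R[["BC"]] - R[["ABC"]] - R[["C"]]
  e <- R[["AB"]] + R[["AC"]] - R[["ABC"]] - R[["A"]]
  f <- R[["AB"]] + R[["BC"]] - R[["ABC"]] - R[["B"]]
  g <- R[["ABC"]] - a - b - cc - d - e - f
  fractions <- c(a_unique_1 = a, b_unique_2 = b, c_unique_3 = cc,
                 d_joint_12 = d, e_joint_23 = e, f_joint_13 = f,
                 g_joint_123 = g, residual = 1 - R[["ABC"]])
  structure(list(fractions = fractions, adj_d2 = R, labels = labels,
                 n = length(y)),
            class = "varpart3")
}

#' @export
print.varpart3 <- function(x, ...) {
  l <- x$labels
  nm <- c(paste0(l[1], " only"), paste0(l[2], " only"),
          paste0(l[3], " only"),
          paste(l[1], "&", l[2]), paste(l[2], "&", l[3]),
          paste(l[1], "&", l[3]), paste(l, collapse = " & "),
          "residual")
  cat(sprintf("Variation partitioning (adjusted D2), n = %d:\n", x$n))
  for (i in seq_along(nm))
    cat(sprintf("  %-24s %8.4f\n", nm[i], x$fractions[i]))
  invisible(x)
}

#' Cross-occurrence GLMs among apomictic cytotypes
#'
#' Within populations containing at least one apomictic cytotype, fits for
#' every unordered cytotype pair the two single-predictor binomial GLMs
#' (each cytotype's occurrence predicting the other's). The Wald z and p
#' are direction-symmetric (they equal the 2x2-table log-odds-ratio
#' statistics); D2 differs by direction and is reported for both.
#' Bonferroni family size defaults to 3 (the three pairs).
#'
#' @param table a `population_table`.
#' @param cytotypes columns treated as apomict occurrence flags.
#' @param family_size Bonferroni family size.
#' @param alpha significance level on adjusted p values.
#' @return data.frame with one row per pair: slope statistics, adjusted
#'   p, and `d2_fwd` (second ~ first) / `d2_rev` (first ~ second).
#' @export
apomict_cross_occurrence <- function(table,
                                     cytotypes = c("present_5x",
                                                   "present_7x",
                                                   "present_8x"),
                                     family_size = 3, alpha = 0.05) {
  stopifnot(all(cytotypes %in% names(table)), length(cytotypes) >= 2)
  apo <- as.matrix(table[cytotypes])
  keep <- rowSums(apo) > 0
  apo <- apo[keep, , drop = FALSE]
  pairs <- utils::combn(cytotypes, 2, simplify = FALSE)
  rows <- list()
  for (pr in pairs) {
    x1 <- apo[, pr[1]]; x2 <- apo[, pr[2]]
    if (sum(x1) == 0 || sum(x2) == 0 || sd(x1) == 0 || sd(x2) == 0) {
      warning("apomict_cross_occurrence: skipping pair ", pr[1], "/",
              pr[2], " (a cytotype is constant in apomict populations)")
      next
    }
    fwd <- suppressWarnings(fit_binomial_glm(x2, data.frame(x = x1)))
    rev <- suppressWarnings(fit_binomial_glm(x1, data.frame(x = x2)))
    zf <- fwd$coefficients$z[2]; zr <- rev$coefficients$z[2]
    tol <- 1e-6 * max(1, abs(zf), abs(zr))   # relative on large z
    if (!fwd$separation && !rev$separation &&
        (abs(zf - zr) > tol ||
         abs(fwd$coefficients$p[2] - rev$coefficients$p[2]) > 1e-6))
      stop("apomict_cross_occurrence: z/p not direction-symmetric for ",
           pr[1], "/", pr[2])
    rows[[length(rows) + 1L]] <- data.frame(
      cytotype_1 = pr[1], cytotype_2 = pr[2],
      estimate = fwd$coefficients$estimate[2],
      se = fwd$coefficients$se[2], z = zf, p = fwd$coefficients$p[2],
      p_adj = min(1, fwd$coefficients$p[2] * family_size),
      d2_fwd = fwd$d2, d2_rev = rev$d2,
      separation = fwd$separation || rev$separation)
  }
  out <- do.call(rbind, rows)
  if (!is.null(out)) out$significant <- out$p_adj < alpha
  out
}
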