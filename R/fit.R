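# Pathway-weight recovery: non-negative least squares on the product
# and gas stoichiometric signatures of the four catabolic routes.

#' Stoichiometric signature matrix of the pathway routes
#'
#' Rows are observable product pools (ethanol, acetate, butyrate, H2 as
#' COD), columns the four routes; each column gives the COD fraction of
#' converted substrate ending in each pool and sums to 1.
#'
#' @return 4 x 4 numeric matrix.
#' @export
pathway_signatures <- function() {
  routes <- .pathway_routes()
  M <- vapply(routes, function(r) {
    c(r$products[c("ethanol", "acetate", "butyrate")], h2 = r$h2_cod)
  }, numeric(4))
  rownames(M) <- c("ethanol", "acetate", "butyrate", "h2")
  M
}

.batch_production_intervals <- function(sim) {
  st <- sim$stream[sim$stream$stream == "out", , drop = FALSE]
  gas <- sim$gas
  out <- list()
  for (b in unique(st$batch)) {
    sb <- st[st$batch == b, , drop = FALSE]
    gb <- gas[gas$batch == b, , drop = FALSE]
    sb <- sb[order(sb$time_d), , drop = FALSE]
    gb <- gb[order(gb$time_d), , drop = FALSE]
    if (nrow(sb) < 2) next
    for (i in 2:nrow(sb)) {
      out[[length(out) + 1L]] <- c(
        ethanol = sb$ethanol_gCOD_L[i] - sb$ethanol_gCOD_L[i - 1],
        acetate = sb$vfa_acetate_gCOD_L[i] - sb$vfa_acetate_gCOD_L[i - 1],
        butyrate = sb$vfa_butyrate_gCOD_L[i] - sb$vfa_butyrate_gCOD_L[i - 1],
        h2 = gas_to_cod(max(gb$h2_mL_L[i] - gb$h2_mL_L[i - 1], 0), "H2")
      )
    }
  }
  if (length(out) == 0) stop("series has no usable sampling intervals")
  do.call(rbind, out)
}

#' Recover pathway weights from a simulated series
#'
#' Least-squares fit of the four pathway weights from the product/gas
#' stoichiometric signatures of the observed per-interval production.
#' For each interval the converted COD is taken as the summed observed
#' production and the production vector is regressed on the signature
#' matrix under non-negativity; the estimates are normalised to sum to
#' one (weights are identified up to the converted share).
#'
#' On noise-free single-pathway data the generating weights are
#' recovered exactly.
#'
#' @param x A `ferm_sim` of kind `"batch"`, or a numeric matrix of
#'   per-interval produced COD with columns `ethanol`, `acetate`,
#'   `butyrate`, `h2`.
#' @param ... Unused.
#' @return Object of class `pathway_fit` with `weights`, `residual`
#'   (root-mean-square of the stacked residuals) and `n_intervals`.
#' @export
fit_pathway_weights <- function(x, ...) {
  if (inherits(x, "ferm_sim")) {
    if (x$kind != "batch") {
      stop("pathway-weight recovery is defined for batch series")
    }
    Y <- .batch_production_intervals(x)
  } else {
    Y <- as.matrix(x)
    need <- c("ethanol", "acetate", "butyrate", "h2")
    if (is.null(colnames(Y)) || !all(need %in% colnames(Y))) {
      stop("production matrix needs columns: ", paste(need, collapse = ", "))
    }
    Y <- Y[, need, drop = FALSE]
  }
  ctot <- rowSums(Y)
  keep <- ctot > .Machine$double.eps^0.5
  if (!any(keep)) {
    stop(structure(
      class = c("vfaferm_undefined", "error", "condition"),
      list(message = "degenerate series: no net production, weights undefined",
           call = NULL)
    ))
  }
  Y <- Y[keep, , drop = FALSE]
  ctot <- ctot[keep]
  M <- pathway_signatures()
  A <- do.call(rbind, lapply(ctot, function(ci) ci * M))
  b <- as.numeric(t(Y)) # row-major stack matching rbind of M blocks
  sol <- pracma::lsqnonneg(A, b)
  wraw <- sol$x
  names(wraw) <- colnames(M)
  weights <- wraw / sum(wraw)
  structure(
    list(weights = weights, residual = sqrt(mean(sol$resid.norm^2 / length(b))),
         n_intervals = nrow(Y), method = "non-negative least squares"),
    class = "pathway_fit"
  )
}

#' @export
coef.pathway_fit <- function(object, ...) object$weights

#' @export
print.pathway_fit <- function(x, ...) {
  cat("Pathway-weight fit (", x$method, ", ", x$n_intervals,
      " intervals)\n", sep = "")
  print(round(x$weights, 4))
  cat("rms residual:", format(x$residual, digits = 4), "\n")
  invisible(x)
}

#' @export
summary.pathway_fit <- function(object, ...) {
  print(object)
  invisible(object)
}
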