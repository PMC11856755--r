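#' Pearson correlation matrix of candidate predictors
#'
#' @param table Numeric matrix or data.frame, observations in rows,
#'   candidate variables in columns.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
pearson_matrix <- function(table) {
  m <- as.matrix(table)
  if (nrow(m) < 3L) stop("need at least 3 observations")
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0))
    stop(sprintf("constant column(s): %s",
                 paste(colnames(m)[sds == 0], collapse = ", ")))
  stats::cor(m, method = "pearson")
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` from the least-squares regression (with
#' intercept) of column j on all other columns. Perfectly collinear
#' columns report `Inf`.
#'
#' @param table Numeric matrix or data.frame (more rows than columns).
#' @return Named numeric vector of VIFs (>= 1, or `Inf`).
#' @export
vif <- function(table) {
  m <- as.matrix(table)
  p <- ncol(m)
  if (p < 2L) return(stats::setNames(rep(1, p), colnames(m)))
  if (nrow(m) <= p) stop("need more observations than variables")
  out <- numeric(p)
  for (j in seq_len(p)) {
    y <- m[, j]; X <- m[, -j, drop = FALSE]
    fit <- stats::lm.fit(cbind(1, X), y)
    rss <- sum(fit$residuals^2)
    tss <- sum((y - mean(y))^2)
    r2 <- 1 - rss / tss
    out[j] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  stats::setNames(out, colnames(m))
}

#' Screen predictors by correlation, VIF, and model contribution
#'
#' Applies the collinearity screen: while any variable pair has
#' `|r| >= r_max` (default 0.8) or any variable has `VIF >= vif_max`
#' (default 10), the violating variable with the lowest model percent
#' contribution is dropped and the statistics are recomputed. Ties are
#' broken by higher VIF, then lexicographic code. Contributions may be a
#' fixed named vector or a function of the surviving codes (so each round
#' can refit the contribution model on the reduced candidate set).
#'
#' @param table Numeric matrix/data.frame of candidate values at
#'   background cells (columns named by variable code).
#' @param contribution Named numeric vector of percent contributions, or
#'   a function `(codes) -> named vector`.
#' @param r_max Pairwise Pearson threshold (default 0.8).
#' @param vif_max VIF threshold (default 10).
#' @return List of class `variable_screen`: `retained` (codes),
#'   `pearson`, `vif`, `contribution` (final values over retained),
#'   `audit` (data.frame, one row per dropped variable).
#' @export
screen_variables <- function(table, contribution, r_max = 0.8, vif_max = 10) {
  m <- as.matrix(table)
  if (is.null(colnames(m))) stop("candidate columns must be named")
  get_contrib <- if (is.function(contribution)) contribution
                 else function(codes) contribution[codes]
  codes <- colnames(m)
  audit <- data.frame(dropped = character(0), reason = character(0),
                      contribution = numeric(0), vif = numeric(0),
                      max_abs_r = numeric(0), round = integer(0))
  round_i <- 0L
  repeat {
    round_i <- round_i + 1L
    cur <- m[, codes, drop = FALSE]
    contrib <- get_contrib(codes)
    if (any(is.na(contrib[codes])))
      stop("contribution missing for some candidates")
    R <- pearson_matrix(cur)
    V <- if (length(codes) > 1L) vif(cur) else stats::setNames(1, codes)
    absR <- abs(R); diag(absR) <- 0
    r_viol <- codes[apply(absR >= r_max, 1, any)]
    v_viol <- codes[V >= vif_max]
    viol <- union(r_viol, v_viol)
    if (!length(viol)) {
      return(structure(list(retained = codes, pearson = R, vif = V,
                            contribution = contrib[codes], audit = audit),
                       class = "variable_screen"))
    }
    if (length(codes) == 1L)
      stop("screening eliminated all variables")
    ord <- order(contrib[viol], -V[viol], viol)
    drop <- viol[ord[1]]
    audit <- rbind(audit, data.frame(
      dropped = drop,
      reason = paste(c(if (drop %in% r_viol) "|r|", if (drop %in% v_viol) "VIF"),
                     collapse = "+"),
      contribution = unname(contrib[drop]), vif = unname(V[drop]),
      max_abs_r = max(absR[drop, ]), round = round_i))
    codes <- setdiff(codes, drop)
    if (!length(codes)) stop("screening eliminated all variables")
  }
}

#' @export
print.variable_screen <- function(x, ...) {
  cat(sprintf("<variable_screen> retained %d variable(s): %s\n",
              length(x$retained), paste(x$retained, collapse = ", ")))
  if (nrow(x$audit))
    cat(sprintf("dropped: %s\n", paste(x$audit$dropped, collapse = ", ")))
  invisible(x)
}

#' Write a screening report CSV
#' @param screen A `variable_screen`.
#' @param path CSV path.
#' @export
write_screen_report <- function(screen, path) {
  ret <- data.frame(variable = screen$retained,
                    decision = "retained",
                    contribution = unname(screen$contribution[screen$retained]),
                    vif = unname(screen$vif[screen$retained]),
                    max_abs_r = vapply(screen$retained, function(v) {
                      r <- abs(screen$pearson[v, ]); r[v] <- 0; max(r)
                    }, numeric(1)))
  drp <- if (nrow(screen$audit))
    data.frame(variable = screen$audit$dropped, decision = "dropped",
               contribution = screen$audit$contribution,
               vif = screen$audit$vif, max_abs_r = screen$audit$max_abs_r)
  else ret[0, ]
  utils::write.csv(rbind(ret, drp), path, row.names = FALSE)
  invisible(path)
}
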