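## Variance-based global sensitivity analysis: Saltelli sampling design
## and Jansen estimators for first-order (main-effect) and total-effect
## Sobol indices, with bootstrap confidence intervals.
##
## For output Y = f(X1..Xk) with independent inputs, the first-order
## index S1_i = Var(E[Y|Xi]) / Var(Y) is the variance share explained
## by Xi alone; the total effect ST_i adds every interaction involving
## Xi.  Estimators (Jansen):
##   S1_i = (V - (1/2N) sum_j (yB_j - yABi_j)^2) / V
##   ST_i = ((1/2N) sum_j (yA_j - yABi_j)^2) / V
## where A and B are two independent N x k designs and ABi is A with
## column i replaced by B's.

#' Saltelli sampling design
#'
#' Generates the base matrices `A` and `B` in the unit hypercube plus
#' the k hybrid matrices `AB[[i]]` (A with column i from B), the
#' standard design for estimating first-order and total-effect Sobol
#' indices at a cost of `(k + 2) * n_base` model runs.
#'
#' The base points are a Sobol' low-discrepancy sequence (see
#' [sobol_sequence()]) under a seeded random binary digital shift --
#' each dimension's binary digits are XORed with a random bit vector,
#' which preserves the digital-net structure exactly (unlike a
#' modulo-1 rotation) while making distinct seeds give distinct,
#' equally accurate designs.  `method = "random"` falls back to plain
#' pseudo-random sampling.
#'
#' @param k Number of input variables (>= 2).
#' @param n_base Base sample size N (>= 64).
#' @param seed Integer seed.
#' @param var_names Optional column names.
#' @param method `"sobol"` (default) or `"random"`.
#' @return List `A`, `B` (N x k matrices), `AB` (list of k matrices),
#'   `n_base`, `k`.
#' @export
saltelli_design <- function(k, n_base, seed = 1L, var_names = NULL,
                            method = c("sobol", "random")) {
  stopifnot(k >= 2, n_base >= 64)
  method <- match.arg(method)
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  u <- if (method == "sobol") {
    q <- sobol_sequence(n_base, 2 * k)
    nbits <- 30L
    denom <- 2^nbits
    shift <- floor(stats::runif(2 * k) * denom)
    qi <- round(q * denom)
    for (j in seq_len(2 * k))
      qi[, j] <- bitwXor(as.integer(qi[, j]), as.integer(shift[j]))
    ## nudge off exact 0 so inverse CDFs with infinite support stay
    ## finite
    (qi + 0.5) / denom
  } else {
    matrix(stats::runif(2 * k * n_base), nrow = n_base)
  }
  A <- u[, seq_len(k), drop = FALSE]
  B <- u[, k + seq_len(k), drop = FALSE]
  if (!is.null(var_names)) {
    stopifnot(length(var_names) == k)
    colnames(A) <- colnames(B) <- var_names
  }
  AB <- lapply(seq_len(k), function(i) {
    M <- A
    M[, i] <- B[, i]
    M
  })
  list(A = A, B = B, AB = AB, n_base = n_base, k = k)
}

#' Map a unit-hypercube design through input quantile functions
#'
#' @param design Output of [saltelli_design()].
#' @param dists List of `fitted_dist` objects, one per design column
#'   (order matters); each must expose a quantile function, which the
#'   empirical family does through its inverse ECDF.
#' @return The design with every matrix mapped to the input scale.
#' @export
map_design <- function(design, dists) {
  stopifnot(length(dists) == design$k)
  map1 <- function(M) {
    out <- vapply(seq_len(ncol(M)), function(i)
      quantile_dist(dists[[i]], M[, i]), numeric(nrow(M)))
    colnames(out) <- colnames(M)
    out
  }
  design$A <- map1(design$A)
  design$B <- map1(design$B)
  design$AB <- lapply(design$AB, map1)
  design
}

#' Sobol indices from model evaluations on a Saltelli design
#'
#' @param y_A,y_B Model output on the `A` and `B` matrices (length N).
#' @param y_AB N x k matrix (or list of k vectors) of outputs on the
#'   hybrid matrices.
#' @param var_names Input variable names (length k).
#' @param n_boot Bootstrap resamples for the confidence half-widths
#'   (default 200; 0 disables).
#' @param conf Confidence level (default 0.95).
#' @param boot_seed Seed for the bootstrap resampling (kept local so
#'   the ambient RNG state is untouched and reruns are identical).
#' @return A `sobol_indices` data frame: `variable`, `main_effect`
#'   (S1, raw -- small negative estimates are retained),
#'   `total_effect` (ST), `S1_ci`, `ST_ci` (half-widths), `n_base`.
#' @export
sobol_indices <- function(y_A, y_B, y_AB, var_names = NULL,
                          n_boot = 200, conf = 0.95, boot_seed = 1L) {
  if (is.list(y_AB)) y_AB <- do.call(cbind, y_AB)
  n <- length(y_A)
  stopifnot(length(y_B) == n, nrow(y_AB) == n)
  k <- ncol(y_AB)
  if (is.null(var_names))
    var_names <- colnames(y_AB) %||% paste0("X", seq_len(k))

  est <- function(idx) {
    a <- y_A[idx]; b <- y_B[idx]; ab <- y_AB[idx, , drop = FALSE]
    V <- stats::var(c(a, b))
    if (!is.finite(V) || V == 0)
      stop("zero output variance: Sobol indices undefined")
    m <- length(idx)
    S1 <- vapply(seq_len(k), function(i)
      (V - sum((b - ab[, i])^2) / (2 * m)) / V, 1)
    ST <- vapply(seq_len(k), function(i)
      sum((a - ab[, i])^2) / (2 * m) / V, 1)
    cbind(S1, ST)
  }

  point <- est(seq_len(n))
  ci <- matrix(NA_real_, k, 2)
  if (n_boot > 0) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(as.integer(boot_seed))
    boots <- vapply(seq_len(n_boot), function(b)
      est(sample.int(n, n, replace = TRUE)),
      matrix(0, k, 2))
    z <- stats::qnorm(1 - (1 - conf) / 2)
    ci <- z * apply(boots, c(1, 2), stats::sd)
  }

  structure(data.frame(variable = var_names,
                       main_effect = point[, 1],
                       total_effect = point[, 2],
                       S1_ci = ci[, 1], ST_ci = ci[, 2],
                       n_base = n, stringsAsFactors = FALSE),
            class = c("sobol_indices", "data.frame"))
}

#' Rank inputs by total effect
#'
#' @param indices A `sobol_indices` data frame.
#' @return The data frame sorted by `total_effect` descending, ties
#'   broken by `main_effect`.
#' @export
rank_drivers <- function(indices) {
  stopifnot(all(c("variable", "main_effect", "total_effect") %in%
                  names(indices)))
  out <- indices[order(-indices$total_effect, -indices$main_effect), ,
                 drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sobol sensitivity of the hazard index to the exposure inputs
#'
#' Builds a Saltelli design over the stochastic inputs of a simulation
#' configuration (EF, IR and the four element concentrations; the
#' fixed factors Ed, AT and W carry no variance and are excluded),
#' evaluates the hazard index on it, and estimates main- and
#' total-effect indices.
#'
#' @param config A [simulation_config()].
#' @param n_base Base sample size (default 1024).
#' @param seed Design seed; defaults to the config seed.
#' @param n_boot Bootstrap resamples (default 200).
#' @param output `"HI"` (default) or `"TCR"`.
#' @return A `sobol_indices` data frame (variables `EF`, `IR`, `C_Cd`,
#'   `C_As`, `C_Hg`, `C_Cu`).
#' @export
sobol_risk <- function(config, n_base = 1024, seed = NULL,
                       n_boot = 200, output = c("HI", "TCR")) {
  stopifnot(inherits(config, "sim_config"))
  output <- match.arg(output)
  seed <- seed %||% config$seed
  dists <- c(list(EF = config$ef_dist, IR = config$ir_dist),
             stats::setNames(config$conc_dists,
                             paste0("C_", WORM_ELEMENTS)))
  vars <- names(dists)
  design <- saltelli_design(length(vars), n_base,
                            seed = substream_seed(seed, "sobol"),
                            var_names = vars)
  design <- map_design(design, unname(dists))

  prof <- config$profile
  eval_rows <- function(M) {
    per_el <- lapply(WORM_ELEMENTS, function(el) {
      row <- prof$elements[prof$elements$element == el, ]
      e <- edi(M[, "EF"], config$Ed, M[, "IR"], M[, paste0("C_", el)],
               config$ba, config$AT, config$W)
      if (output == "HI")
        hq(e, row$RfD, prof$safety_factor)
      else if (row$carcinogen) cr(e, row$CSF) else rep(0, nrow(M))
    })
    Reduce(`+`, per_el)
  }
  y_A <- eval_rows(design$A)
  y_B <- eval_rows(design$B)
  y_AB <- vapply(design$AB, eval_rows, numeric(n_base))
  sobol_indices(y_A, y_B, y_AB, var_names = vars, n_boot = n_boot,
                boot_seed = substream_seed(seed, "sobol_boot"))
}

#' One-at-a-time tornado diagnostic
#'
#' Simple local sensitivity: each input in turn is moved from its `lo`
#' to its `hi` quantile while the others sit at their medians, and the
#' resulting output swing is reported.  A coarse complement to the
#' variance-based indices, useful as a quick screen.
#'
#' @inheritParams sobol_risk
#' @param lo,hi Quantiles defining the swing (defaults 0.05, 0.95).
#' @return Data frame `variable`, `low`, `high`, `swing`, sorted by
#'   absolute swing.
#' @export
tornado_risk <- function(config, lo = 0.05, hi = 0.95,
                         output = c("HI", "TCR")) {
  stopifnot(inherits(config, "sim_config"))
  output <- match.arg(output)
  dists <- c(list(EF = config$ef_dist, IR = config$ir_dist),
             stats::setNames(config$conc_dists,
                             paste0("C_", WORM_ELEMENTS)))
  med <- vapply(dists, quantile_dist, 1, p = 0.5)
  eval_point <- function(x) {
    M <- matrix(x, nrow = 1, dimnames = list(NULL, names(dists)))
    prof <- config$profile
    vals <- vapply(WORM_ELEMENTS, function(el) {
      row <- prof$elements[prof$elements$element == el, ]
      e <- edi(M[, "EF"], config$Ed, M[, "IR"], M[, paste0("C_", el)],
               config$ba, config$AT, config$W)
      if (output == "HI") hq(e, row$RfD, prof$safety_factor)
      else if (row$carcinogen) cr(e, row$CSF) else 0
    }, 1)
    sum(vals)
  }
  out <- do.call(rbind, lapply(names(dists), function(v) {
    x_lo <- med; x_lo[[v]] <- quantile_dist(dists[[v]], lo)
    x_hi <- med; x_hi[[v]] <- quantile_dist(dists[[v]], hi)
    data.frame(variable = v, low = eval_point(x_lo),
               high = eval_point(x_hi),
               swing = eval_point(x_hi) - eval_point(x_lo),
               stringsAsFactors = FALSE)
  }))
  out[order(-abs(out$swing)), , drop = FALSE]
}

#' Write Sobol indices as CSV
#'
#' Small negative main-effect estimates (estimator noise around zero)
#' are written raw; [plot_sobol()] clips them for display only.
#'
#' @param indices A `sobol_indices` data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sobol <- function(indices, path) {
  utils::write.csv(as.data.frame(indices), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Bar chart of main- and total-effect Sobol indices
#'
#' @param indices A `sobol_indices` data frame.
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_sobol <- function(indices, title = "Sobol sensitivity of HI") {
  df <- rank_drivers(indices)
  long <- rbind(
    data.frame(variable = df$variable, effect = "main effect",
               value = pmax(df$main_effect, 0)),
    data.frame(variable = df$variable, effect = "total effect",
               value = pmax(df$total_effect, 0)))
  long$variable <- factor(long$variable, levels = rev(df$variable))
  ggplot2::ggplot(long,
                  ggplot2::aes(x = variable, y = value,
                               fill = effect)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(title = title, x = NULL, y = "Sobol index",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
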