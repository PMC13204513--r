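#' Simulate replicate concentration sets on the cohort's actual design
#'
#' For each replicate: individual parameters are drawn per patient from the
#' model's inter-individual variability, concentrations are computed at the
#' patient's real sampling times on the real dosing history, residual error
#' is added (additive and/or proportional per the model's `residual` spec),
#' and the BLQ censoring rule applied to the observations is applied to the
#' simulated values too, so simulated and observed distributions remain
#' comparable.
#'
#' @param model A [poppk_model()] with `iiv` and `residual` specs.
#' @param design A list with one element per patient, each a list with
#'   `covariates` (a [covariate_set()] or list of them), `history` (a
#'   [dosing_history()]) and `times` (sampling times, h).
#' @param n_rep Number of replicates (default 1000).
#' @param seed Optional integer seed (private RNG state).
#' @param blq_limit,blq_replacement BLQ censoring rule applied to simulated
#'   values; set `blq_limit = 0` to disable.
#' @return A numeric matrix, one row per observation (patients stacked in
#'   design order), one column per replicate.  Row order matches
#'   `unlist(lapply(design, [[, "times"))`.
#' @export
simulate_replicates <- function(model, design, n_rep = 1000, seed = NULL,
                                blq_limit = 4, blq_replacement = 2) {
  stopifnot(inherits(model, "poppk_model"), is.list(design), n_rep >= 1)
  if (is.null(model$residual)) {
    stop("model declares no residual-error spec; simulation is undefined",
         call. = FALSE)
  }
  if (is.null(model$iiv)) {
    stop("model declares no iiv spec; use zero variances for no IIV",
         call. = FALSE)
  }
  add_sd <- model$residual$additive_sd %||% 0
  prop_cv <- model$residual$proportional_cv %||% 0
  n_obs <- sum(vapply(design, function(d) length(d$times), integer(1)))
  out <- matrix(NA_real_, nrow = n_obs, ncol = n_rep)
  with_seed(seed, {
    row0 <- 0L
    for (d in design) {
      covs <- if (inherits(d$covariates, "covariate_set")) {
        list(d$covariates)
      } else d$covariates
      nt <- length(d$times)
      if (nt == 0) next
      # map each sampling time to its carried-forward covariate record and
      # evaluate typical parameters once per record
      cov_times <- vapply(covs, function(x) x$measurement_time_h, numeric(1))
      ord <- order(cov_times)
      covs <- covs[ord]; cov_times <- cov_times[ord]
      idx <- findInterval(d$times, cov_times)
      if (any(idx == 0)) {
        stop("no covariate record at or before a VPC sampling time",
             call. = FALSE)
      }
      typ <- lapply(unique(idx), function(j) evaluate_model(model, covs[[j]]))
      names(typ) <- as.character(unique(idx))
      iiv_cl <- model$iiv["cl_L_h"]
      iiv_v <- model$iiv["v_L"]
      iiv_cl <- if (is.na(iiv_cl)) 0 else iiv_cl
      iiv_v <- if (is.na(iiv_v)) 0 else iiv_v
      for (r in seq_len(n_rep)) {
        eta_cl <- stats::rnorm(1, 0, sqrt(iiv_cl))
        eta_v <- stats::rnorm(1, 0, sqrt(iiv_v))
        pred <- numeric(nt)
        for (j in unique(idx)) {
          p <- typ[[as.character(j)]]
          p$cl_L_h <- p$cl_L_h * exp(eta_cl)
          p$v_L <- p$v_L * exp(eta_v)
          sel <- idx == j
          pred[sel] <- concentration_at(p, d$history, d$times[sel])
        }
        noisy <- pred * (1 + stats::rnorm(nt, 0, prop_cv)) +
          stats::rnorm(nt, 0, add_sd)
        noisy[noisy < 0] <- 0
        if (blq_limit > 0) noisy[noisy < blq_limit] <- blq_replacement
        out[row0 + seq_len(nt), r] <- noisy
      }
      row0 <- row0 + nt
    }
  })
  out
}

#' Summarise a visual predictive check
#'
#' Bins observations by time (typically time after most recent dose),
#' computes the requested percentiles of the pooled simulated values per bin
#' and overlays the observed percentiles, and reports the percentage of
#' observations falling inside the outer simulated band.
#'
#' @param observed Numeric vector of observed concentrations.
#' @param replicates Matrix from [simulate_replicates()] (rows align with
#'   `observed`).
#' @param times Numeric vector of binning times, same length as `observed`;
#'   default a single bin.
#' @param band Percentile levels (lower, median, upper), default
#'   `c(5, 50, 95)`.
#' @param n_bins Number of quantile-spaced time bins (ignored when `bin_edges`
#'   given).
#' @param bin_edges Optional explicit bin edges.
#' @return A list of class `vpc_result`: `table` (bin, level, simulated,
#'   observed), `bin_edges`, `coverage_pct`.
#' @export
vpc_summary <- function(observed, replicates, times = NULL,
                        band = c(5, 50, 95), n_bins = 4, bin_edges = NULL) {
  stopifnot(is.numeric(observed), length(observed) >= 1,
            is.matrix(replicates), nrow(replicates) == length(observed),
            length(band) == 3, all(diff(band) > 0))
  if (is.null(times)) times <- rep(0, length(observed))
  if (is.null(bin_edges)) {
    if (n_bins > 1) {
      probs <- seq(0, 1, length.out = n_bins + 1)
      bin_edges <- stats::quantile(times, probs, names = FALSE)
    } else {
      bin_edges <- range(times)
    }
  }
  bin_edges <- unique(bin_edges)
  if (length(bin_edges) < 2) bin_edges <- c(bin_edges, bin_edges + 1)
  bin <- cut(times, breaks = bin_edges, include.lowest = TRUE)
  p <- band / 100
  rows <- list(); covered <- logical(length(observed))
  for (b in levels(bin)) {
    idx <- which(bin == b)
    if (!length(idx)) next
    sim <- as.vector(replicates[idx, , drop = FALSE])
    sq <- stats::quantile(sim, p, names = FALSE)
    oq <- stats::quantile(observed[idx], p, names = FALSE)
    covered[idx] <- observed[idx] >= sq[1] & observed[idx] <= sq[3]
    rows[[b]] <- data.frame(bin = b, level = band, simulated = sq,
                            observed = oq)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(table = tab, bin_edges = bin_edges,
                 coverage_pct = 100 * mean(covered)),
            class = "vpc_result")
}

#' @export
print.vpc_result <- function(x, ...) {
  cat(sprintf("<vpc_result> %d bins, %.1f%% of observations inside the outer simulated band\n",
              length(unique(x$table$bin)), x$coverage_pct))
  print(x$table)
  invisible(x)
}

#' Plot a visual predictive check
#'
#' Base-graphics plot of the simulated percentile band per bin with observed
#' percentiles overlaid.
#'
#' @param x A `vpc_result`.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.vpc_result <- function(x, ...) {
  tab <- x$table
  bins <- unique(tab$bin)
  mids <- seq_along(bins)
  levs <- sort(unique(tab$level))
  get_level <- function(df, lv, col) df[[col]][df$level == lv]
  lo <- vapply(bins, function(b) get_level(tab[tab$bin == b, ], levs[1],
                                           "simulated"), numeric(1))
  md <- vapply(bins, function(b) get_level(tab[tab$bin == b, ], levs[2],
                                           "simulated"), numeric(1))
  hi <- vapply(bins, function(b) get_level(tab[tab$bin == b, ], levs[3],
                                           "simulated"), numeric(1))
  obs_md <- vapply(bins, function(b) get_level(tab[tab$bin == b, ], levs[2],
                                               "observed"), numeric(1))
  graphics::plot(mids, md, type = "l", ylim = range(c(lo, hi, obs_md)),
                 xaxt = "n", xlab = "time bin",
                 ylab = "concentration (mg/L)", ...)
  graphics::axis(1, at = mids, labels = bins, cex.axis = 0.7)
  graphics::polygon(c(mids, rev(mids)), c(lo, rev(hi)),
                    col = grDevices::adjustcolor("steelblue", 0.3),
                    border = NA)
  graphics::lines(mids, md, col = "steelblue", lwd = 2)
  graphics::points(mids, obs_md, pch = 19)
  invisible(x)
}
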