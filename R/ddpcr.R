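#' Droplet digital PCR well counts
#'
#' @param n total number of droplets.
#' @param nmu droplets positive for the mutant probe.
#' @param nDNAconc droplets positive for the mutant and/or wild-type probe.
#' @return object of class `ddpcr_well`.
#' @export
ddpcr_well <- function(n, nmu, nDNAconc) {
  if (n <= 0) stop2("total droplet count must be positive")
  if (nmu < 0 || nDNAconc < 0) stop2("droplet counts must be non-negative")
  if (nmu > nDNAconc)
    stop2("inconsistent counts: nmu exceeds nDNAconc")
  if (nDNAconc > n)
    stop2("inconsistent counts: nDNAconc exceeds total droplets")
  structure(list(n = as.integer(n), nmu = as.integer(nmu),
                 nDNAconc = as.integer(nDNAconc)), class = "ddpcr_well")
}

#' Poisson-corrected mutant allele fraction from ddPCR droplet counts
#'
#' Droplet occupancy is Poisson, so positive-droplet fractions map to
#' concentrations (copies per droplet) via
#' `Mmu = -ln(1 - nmu/n)` and `MDNAconc = -ln(1 - nDNAconc/n)`, and the
#' mutant allele fraction is `maf = Mmu / MDNAconc`. Counts from multiple
#' wells of one sample are pooled by summing droplets before the transform
#' (the maximum-likelihood combination for a shared concentration);
#' per-well estimates are reported alongside.
#'
#' @param wells a [ddpcr_well()] or list of them (one sample).
#' @param conf_level if non-`NULL`, attach a simple binomially-propagated
#'   confidence interval for `maf` at this level. This interval is an extra
#'   convenience output of the estimator, delta-method based.
#' @return object of class `maf_result`: list with `Mmu`, `MDNAconc`, `maf`,
#'   `pooled` ([ddpcr_well()] of summed counts), `per_well` (data.frame of
#'   per-well estimates) and optionally `maf_ci`.
#' @export
poisson_maf <- function(wells, conf_level = NULL) {
  if (inherits(wells, "ddpcr_well")) wells <- list(wells)
  stopifnot(length(wells) >= 1L,
            all(vapply(wells, inherits, logical(1), "ddpcr_well")))
  tot <- ddpcr_well(n = sum(vapply(wells, `[[`, integer(1), "n")),
                    nmu = sum(vapply(wells, `[[`, integer(1), "nmu")),
                    nDNAconc = sum(vapply(wells, `[[`, integer(1),
                                          "nDNAconc")))
  if (tot$nDNAconc == tot$n)
    stop2("saturated well: every droplet is DNA-positive (log undefined)")
  if (tot$nDNAconc == 0L)
    stop2("no template: no DNA-positive droplets")
  est <- function(w) {
    Mmu <- -log(1 - w$nmu / w$n)
    MDNA <- -log(1 - w$nDNAconc / w$n)
    c(Mmu = Mmu, MDNAconc = MDNA, maf = Mmu / MDNA)
  }
  e <- est(tot)
  per_well <- do.call(rbind, lapply(seq_along(wells), function(i) {
    w <- wells[[i]]
    ok <- w$nDNAconc > 0L && w$nDNAconc < w$n
    data.frame(well = i, n = w$n, nmu = w$nmu, nDNAconc = w$nDNAconc,
               Mmu = if (ok) -log(1 - w$nmu / w$n) else NA_real_,
               MDNAconc = if (ok) -log(1 - w$nDNAconc / w$n) else NA_real_,
               maf = if (ok) -log(1 - w$nmu / w$n) /
                       -log(1 - w$nDNAconc / w$n) else NA_real_)
  }))
  out <- list(Mmu = unname(e["Mmu"]), MDNAconc = unname(e["MDNAconc"]),
              maf = unname(e["maf"]), pooled = tot, per_well = per_well)
  if (!is.null(conf_level)) {
    ## delta method on the two positive-droplet fractions
    n <- tot$n
    p1 <- tot$nmu / n; p2 <- tot$nDNAconc / n
    vM1 <- p1 * (1 - p1) / n / (1 - p1)^2
    vM2 <- p2 * (1 - p2) / n / (1 - p2)^2
    if (e["Mmu"] > 0) {
      vlog <- vM1 / e["Mmu"]^2 + vM2 / e["MDNAconc"]^2
      z <- stats::qnorm(1 - (1 - conf_level) / 2)
      out$maf_ci <- unname(e["maf"] * exp(c(-1, 1) * z * sqrt(vlog)))
    } else {
      out$maf_ci <- c(0, NA_real_)
    }
  }
  class(out) <- "maf_result"
  out
}

#' @export
print.maf_result <- function(x, ...) {
  cat(sprintf(
    "<maf_result> Mmu=%.4g MDNAconc=%.4g copies/droplet, maf=%.4g (%d wells)\n",
    x$Mmu, x$MDNAconc, x$maf, nrow(x$per_well)))
  invisible(x)
}

#' Estimate mutant allele fractions from a well table
#'
#' @param wells_df data.frame with columns `sample`, `well`, `n`, `nmu`,
#'   `nDNAconc`.
#' @return data.frame with one row per sample: `sample`, `Mmu`, `MDNAconc`,
#'   `maf`.
#' @export
ddpcr_table <- function(wells_df) {
  stopifnot(all(c("sample", "n", "nmu", "nDNAconc") %in% names(wells_df)))
  out <- lapply(split(wells_df, wells_df$sample), function(d) {
    ws <- lapply(seq_len(nrow(d)), function(i)
      ddpcr_well(d$n[i], d$nmu[i], d$nDNAconc[i]))
    r <- poisson_maf(ws)
    data.frame(sample = d$sample[1], Mmu = r$Mmu, MDNAconc = r$MDNAconc,
               maf = r$maf, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
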