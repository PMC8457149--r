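#' Read and write the pipeline's tabular interchange formats
#'
#' All interchange is plain CSV. Forcing: `year`, `doy`, `precip_mm`,
#' `vpd_kpa`. Water-potential ensembles travel as long CSV with columns
#' `realization`, `layer`, `day`, `psi_mpa` plus a header-free sidecar of grid
#' depths is unnecessary because the grid is reconstructed from `depth_m`.
#'
#' @param x object to write.
#' @param path file path.
#' @name io
NULL

#' @rdname io
#' @export
write_forcing_csv <- function(x, path) {
  utils::write.csv(x[, c("year", "doy", "precip_mm", "vpd_kpa")], path,
                   row.names = FALSE)
}

#' @rdname io
#' @export
read_forcing_csv <- function(path) {
  utils::read.csv(path)
}

#' @rdname io
#' @export
write_ensemble_csv <- function(x, path) {
  stopifnot(inherits(x, "wp_ensemble"))
  d <- dim(x$psi)
  long <- data.frame(
    realization = rep(seq_len(d[1]), times = d[2] * d[3]),
    layer = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    day = rep(seq_len(d[3]), each = d[1] * d[2]),
    depth_m = rep(rep(x$grid$z, each = d[1]), times = d[3]),
    psi_mpa = as.numeric(x$psi))
  utils::write.csv(long, path, row.names = FALSE)
}

#' @rdname io
#' @export
read_ensemble_csv <- function(path) {
  long <- utils::read.csv(path)
  d <- c(max(long$realization), max(long$layer), max(long$day))
  z <- sort(unique(long$depth_m))
  psi <- array(NA_real_, dim = d)
  psi[cbind(long$realization, long$layer, long$day)] <- long$psi_mpa
  structure(list(psi = psi, params = NULL,
                 objective = rep(NA_real_, d[1]),
                 grid = soil_grid(z)), class = "wp_ensemble")
}
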