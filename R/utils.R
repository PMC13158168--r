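# internal helpers shared across modules

REGIONS <- c("thermal", "epithermal", "fast")
FOILS <- c("Au", "Mn", "Al")
BARN_CM2 <- 1e-24
PSV_SV <- 1e-12
AVOGADRO <- 6.02214076e23

extdataFile <- function(name) {
  path <- system.file("extdata", name, package = "bnctdose")
  if (!nzchar(path)) {
    stop("data file not found in package extdata: ", name)
  }
  path
}

# two-column energy/value CSV with '#' comment header lines
readEnergyTable <- function(path, valueName = "value") {
  df <- utils::read.csv(path, comment.char = "#", header = TRUE)
  names(df) <- c("energy_MeV", valueName)
  if (is.unsorted(df$energy_MeV, strictly = TRUE)) {
    stop("energies in ", path, " must be strictly increasing")
  }
  df
}

# log-log interpolation with hard domain bounds (no clamping); zero or
# negative y falls back to linear interpolation on the affected segment
evalLogLog <- function(x, xtab, ytab) {
  if (any(x < xtab[1] | x > xtab[length(xtab)])) {
    bad <- x[x < xtab[1] | x > xtab[length(xtab)]]
    stop("energy outside tabulated range [", format(xtab[1]), ", ",
         format(xtab[length(xtab)]), "] MeV: ", paste(format(bad), collapse = ", "))
  }
  i <- findInterval(x, xtab, rightmost.closed = TRUE)
  i[i < 1] <- 1L
  x1 <- xtab[i]; x2 <- xtab[i + 1]
  y1 <- ytab[i]; y2 <- ytab[i + 1]
  out <- numeric(length(x))
  at_node <- x == x1
  out[at_node] <- y1[at_node]
  mid <- !at_node
  if (any(mid)) {
    ll <- mid & y1 > 0 & y2 > 0
    out[ll] <- exp(log(y1[ll]) + log(y2[ll] / y1[ll]) *
                     log(x[ll] / x1[ll]) / log(x2[ll] / x1[ll]))
    lin <- mid & !(y1 > 0 & y2 > 0)
    out[lin] <- y1[lin] + (y2[lin] - y1[lin]) *
      (x[lin] - x1[lin]) / (x2[lin] - x1[lin])
  }
  out
}

# log-normal multiplicative noise with unit mean and given relative SD
unitMeanLnormFactor <- function(n, relSd) {
  if (relSd < 0) stop("relative SD must be >= 0")
  if (relSd == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + relSd^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

stopifnotScalar <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(name, " must be a finite numeric scalar")
  }
  if (positive && x <= 0) stop(name, " must be > 0")
  invisible(x)
}
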