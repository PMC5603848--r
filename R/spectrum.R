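#' Accumulate fragment statistical charges over production runs
#'
#' The total relative intensity of a fragment is the sum of its
#' statistical charges over the ensemble of production runs; accumulation
#' groups by canonical formula and is associative, so batching and run
#' order never change the result.
#'
#' @param records List of [fragment_record()]s pooled from any number of
#'   runs (or a list of `production_result`s).
#' @return Named numeric vector: canonical formula key -> total charge.
#' @export
accumulate_charges <- function(records) {
  if (length(records) && inherits(records[[1]], "production_result"))
    records <- unlist(lapply(records, function(r) r$fragment_records),
                      recursive = FALSE)
  out <- numeric(0)
  for (r in records) {
    key <- formula_key(r$formula)
    out[key] <- (if (key %in% names(out)) out[[key]] else 0) +
      r$statistical_charge
  }
  out
}

#' Build the isotope-convolved stick spectrum
#'
#' Distributes each accumulated formula's charge over its natural
#' isotope pattern ([isotope_pattern()]), sums the results on the unit
#' mass grid, and normalizes to the base peak at relative intensity 100.
#' Raw charges per m/z contributor are retained as provenance.
#'
#' @param accum Named charge vector from [accumulate_charges()].
#' @param prune Isotopologue pruning threshold (default 1e-4).
#' @return Object of class `mass_spectrum`: data.frame `sticks` with
#'   integer `mz` (strictly increasing) and `intensity` (percent of base
#'   peak, in (0, 100]), plus `provenance` (list keyed by m/z of
#'   contributing formulas and raw charges) and `total_charge`.
#' @export
convolve_and_bin <- function(accum, prune = 1e-4) {
  intens <- numeric(0)
  prov <- list()
  for (key in names(accum)) {
    pat <- isotope_pattern(ms_formula(key), prune_threshold = prune)
    for (r in seq_len(nrow(pat))) {
      mz <- as.character(pat$mz[r])
      w <- accum[[key]] * pat$abundance[r]
      intens[mz] <- (if (mz %in% names(intens)) intens[[mz]] else 0) + w
      prov[[mz]] <- c(prov[[mz]], stats::setNames(w, key))
    }
  }
  mz <- as.integer(names(intens))
  ord <- order(mz)
  raw <- unname(intens)[ord]
  sticks <- data.frame(mz = mz[ord], intensity = 100 * raw / max(raw))
  structure(list(sticks = sticks, provenance = prov[as.character(mz[ord])],
                 total_charge = sum(raw)),
            class = "mass_spectrum")
}

#' Construct a mass spectrum directly from sticks
#'
#' @param mz Integer m/z values.
#' @param intensity Intensities (rescaled so the base peak is 100).
#' @return A `mass_spectrum`.
#' @export
mass_spectrum <- function(mz, intensity) {
  stopifnot(length(mz) == length(intensity), all(intensity > 0))
  if (!length(mz))
    return(structure(list(sticks = data.frame(mz = integer(0),
                                              intensity = numeric(0)),
                          provenance = NULL, total_charge = 0),
                     class = "mass_spectrum"))
  ord <- order(mz)
  mz <- as.integer(mz[ord]); intensity <- intensity[ord]
  if (anyDuplicated(mz)) stop("duplicate m/z values", call. = FALSE)
  structure(list(sticks = data.frame(mz = mz,
                                     intensity = 100 * intensity /
                                       max(intensity)),
                 provenance = NULL, total_charge = sum(intensity)),
            class = "mass_spectrum")
}

#' @export
print.mass_spectrum <- function(x, ...) {
  cat("<mass_spectrum> ", nrow(x$sticks), " sticks, base peak m/z ",
      x$sticks$mz[which.max(x$sticks$intensity)], "\n", sep = "")
  top <- x$sticks[order(-x$sticks$intensity), ][seq_len(min(8, nrow(x$sticks))), ]
  for (i in seq_len(nrow(top)))
    cat(sprintf("  m/z %4d  %6.2f\n", top$mz[i], top$intensity[i]))
  invisible(x)
}

#' Write a spectrum in NIST MSP format
#'
#' @param spec A `mass_spectrum` (non-empty).
#' @param metadata Named list; `Name` and `Formula` are emitted as MSP
#'   header fields.
#' @param prune_percent Sticks below this percent of the base peak are
#'   omitted (default 0.1, the usual figure-legibility convention; 0
#'   keeps everything).
#' @return MSP text (single string).
#' @export
write_msp <- function(spec, metadata = list(Name = "simulated"),
                      prune_percent = 0.1) {
  st <- .pruned_sticks(spec, prune_percent)
  header <- vapply(names(metadata), function(k)
    paste0(k, ": ", metadata[[k]]), character(1))
  paste(c(header, paste0("Num Peaks: ", nrow(st)),
          sprintf("%d %.6g", st$mz, st$intensity), ""),
        collapse = "\n")
}

#' Read an MSP spectrum
#' @param text MSP text (as written by [write_msp()]).
#' @return A `mass_spectrum`.
#' @export
read_msp <- function(text) {
  lines <- if (length(text) == 1L) strsplit(text, "\n")[[1]] else text
  npk_line <- grep("^Num Peaks:", lines)
  if (!length(npk_line)) stop("not MSP: missing 'Num Peaks:'", call. = FALSE)
  n <- as.integer(sub("^Num Peaks:\\s*", "", lines[npk_line[1]]))
  peaks <- lines[(npk_line[1] + 1L):length(lines)]
  peaks <- peaks[nzchar(trimws(peaks))][seq_len(n)]
  parts <- do.call(rbind, strsplit(trimws(peaks), "[[:space:];]+"))
  mass_spectrum(as.integer(parts[, 1]), as.numeric(parts[, 2]))
}

#' Write a spectrum in JCAMP-DX 4.24 format
#'
#' Emits `##DATA TYPE=MASS SPECTRUM` with `##XYDATA=(XY..XY)` point
#' pairs.
#'
#' @inheritParams write_msp
#' @param metadata Named list; `TITLE` defaults to "simulated".
#' @return JCAMP-DX text.
#' @export
write_jcamp <- function(spec, metadata = list(TITLE = "simulated"),
                        prune_percent = 0.1) {
  st <- .pruned_sticks(spec, prune_percent)
  paste(c(
    paste0("##TITLE=", metadata$TITLE %||% "simulated"),
    "##JCAMP-DX=4.24",
    "##DATA TYPE=MASS SPECTRUM",
    "##XUNITS=M/Z", "##YUNITS=RELATIVE INTENSITY",
    paste0("##NPOINTS=", nrow(st)),
    "##XYDATA=(XY..XY)",
    sprintf("%d,%.6g", st$mz, st$intensity),
    "##END=", ""), collapse = "\n")
}

#' Read a JCAMP-DX spectrum written by [write_jcamp()]
#' @param text JCAMP-DX text.
#' @return A `mass_spectrum`.
#' @export
read_jcamp <- function(text) {
  lines <- if (length(text) == 1L) strsplit(text, "\n")[[1]] else text
  start <- grep("^##XYDATA", lines)
  if (!length(start)) stop("not JCAMP-DX: missing ##XYDATA", call. = FALSE)
  end <- grep("^##END", lines)
  body <- lines[(start[1] + 1L):(end[1] - 1L)]
  parts <- do.call(rbind, strsplit(trimws(body), ","))
  mass_spectrum(as.integer(parts[, 1]), as.numeric(parts[, 2]))
}

.pruned_sticks <- function(spec, prune_percent) {
  stopifnot(inherits(spec, "mass_spectrum"))
  st <- spec$sticks
  if (!nrow(st)) stop("empty spectrum", call. = FALSE)
  st[st$intensity >= prune_percent, , drop = FALSE]
}

#' Weighted cosine similarity between two stick spectra
#'
#' Dot-product similarity on the union m/z grid with intensities weighted
#' by `mz^mz_weight_power` (power 0 gives the plain cosine; powers of
#' 1–3 emphasize the structurally informative high-mass peaks, as in
#' standard library matching).
#'
#' @param a,b `mass_spectrum` objects.
#' @param mz_weight_power Exponent on m/z in the weighting (default 0).
#' @return Similarity in `[0, 1]`.
#' @export
cosine_similarity <- function(a, b, mz_weight_power = 0) {
  if (!nrow(a$sticks) && !nrow(b$sticks))
    stop("both spectra empty", call. = FALSE)
  grid <- sort(union(a$sticks$mz, b$sticks$mz))
  va <- vb <- numeric(length(grid))
  va[match(a$sticks$mz, grid)] <- a$sticks$intensity
  vb[match(b$sticks$mz, grid)] <- b$sticks$intensity
  w <- as.numeric(grid)^mz_weight_power
  va <- va * w; vb <- vb * w
  denom <- sqrt(sum(va^2)) * sqrt(sum(vb^2))
  if (denom == 0) return(0)
  sum(va * vb) / denom
}

#' Head-to-tail comparison plot of two spectra
#'
#' Computed spectrum up, reference down — the conventional layout for
#' visual comparison of a simulated and an experimental EI-MS.
#'
#' @param computed,reference `mass_spectrum` objects.
#' @param main Plot title.
#' @export
plot_head_to_tail <- function(computed, reference,
                              main = "computed (up) vs reference (down)") {
  xlim <- range(c(computed$sticks$mz, reference$sticks$mz)) + c(-2, 2)
  graphics::plot(NULL, xlim = xlim, ylim = c(-105, 105), xlab = "m/z",
                 ylab = "relative intensity", main = main)
  graphics::abline(h = 0)
  graphics::segments(computed$sticks$mz, 0, computed$sticks$mz,
                     computed$sticks$intensity, col = "blue")
  graphics::segments(reference$sticks$mz, 0, reference$sticks$mz,
                     -reference$sticks$intensity, col = "red")
  invisible(NULL)
}
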