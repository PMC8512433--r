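#' Write a spectral library in MSP format
#'
#' Records carry `Name:`, `RI:` (when present), `Num Peaks:` and one
#' `mz intensity` pair per line, the plain-text convention EI libraries use.
#'
#' @param specs List of library spectra: each a list with `name`,
#'   `peaks` (matrix mz/intensity) and optional `ri_lit`; [compound_spec()]
#'   objects are accepted (their `true_ri` becomes the literature RI).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_library <- function(specs, path) {
  lines <- unlist(lapply(specs, function(s) {
    if (inherits(s, "compound_spec"))
      s <- list(name = s$name, peaks = s$spectrum, ri_lit = s$true_ri)
    pk <- s$peaks
    c(paste0("Name: ", s$name),
      if (!is.null(s$ri_lit) && !is.na(s$ri_lit)) paste0("RI: ", format(s$ri_lit)),
      paste0("Num Peaks: ", nrow(pk)),
      sprintf("%d %g", as.integer(pk[, 1]), pk[, 2]),
      "")
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read an MSP spectral library
#'
#' @param path MSP file.
#' @return List of `library_spectrum` objects (`name`, `peaks` sorted by m/z
#'   and rescaled to base peak 999, `ri_lit` or `NA`).
#' @export
read_library <- function(path) {
  lines <- trimws(readLines(path))
  starts <- grep("^Name:", lines, ignore.case = TRUE)
  if (!length(starts)) return(list())
  ends <- c(starts[-1] - 1L, length(lines))
  lapply(seq_along(starts), function(k) {
    rec <- lines[starts[k]:ends[k]]
    name <- trimws(sub("^Name:", "", rec[1], ignore.case = TRUE))
    ri <- NA_real_
    ri_line <- grep("^RI:", rec, ignore.case = TRUE)
    if (length(ri_line)) ri <- as.numeric(sub("^RI:", "", rec[ri_line[1]], ignore.case = TRUE))
    np_line <- grep("^Num Peaks:", rec, ignore.case = TRUE)
    if (!length(np_line)) stopf("MSP record '%s': missing 'Num Peaks'", name)
    np <- as.integer(sub("^Num Peaks:", "", rec[np_line[1]], ignore.case = TRUE))
    body <- rec[(np_line[1] + 1):length(rec)]
    body <- body[nzchar(body)]
    toks <- as.numeric(unlist(strsplit(paste(body, collapse = " "), "[[:space:];,]+")))
    toks <- toks[!is.na(toks)]
    if (length(toks) != 2 * np)
      stopf("MSP record '%s': 'Num Peaks: %d' but %d values found", name, np, length(toks))
    pk <- matrix(toks, ncol = 2, byrow = TRUE, dimnames = list(NULL, c("mz", "intensity")))
    pk <- pk[order(pk[, "mz"]), , drop = FALSE]
    if (nrow(pk)) pk[, "intensity"] <- pk[, "intensity"] / max(pk[, "intensity"]) * 999
    structure(list(name = name, peaks = pk, ri_lit = ri), class = "library_spectrum")
  })
}

#' Build a synthetic spectral library with decoys
#'
#' The true compound panel plus `n_decoys` decoy entries: perturbed copies of
#' true spectra whose literature RIs are shifted by 30-80 index units, so a
#' correct two-step identification (match factor plus RI gate) must reject
#' them even when the spectral match is good.
#'
#' @param compounds List of [compound_spec()] objects.
#' @param n_decoys Number of decoy entries.
#' @param seed Seed (private RNG stream).
#' @return List of `library_spectrum` objects; decoys are named
#'   `"Decoy-<original name>"`.
#' @export
synthetic_spectral_library <- function(compounds, n_decoys = 10, seed = 2207L) {
  lib <- lapply(compounds, function(s)
    structure(list(name = s$name, peaks = s$spectrum, ri_lit = s$true_ri),
              class = "library_spectrum"))
  if (n_decoys > 0) {
    decoys <- with_local_seed(seed, {
      src <- sample(seq_along(compounds), n_decoys,
                    replace = n_decoys > length(compounds))
      lapply(seq_len(n_decoys), function(k) {
        s <- compounds[[src[k]]]
        pk <- s$spectrum
        pk[, "intensity"] <- pmax(1, pk[, "intensity"] * stats::runif(nrow(pk), 0.7, 1.3))
        pk[, "intensity"] <- pk[, "intensity"] / max(pk[, "intensity"]) * 999
        shift <- sample(c(-1, 1), 1) * stats::runif(1, 30, 80)
        structure(list(name = paste0("Decoy-", s$name), peaks = pk,
                       ri_lit = s$true_ri + shift), class = "library_spectrum")
      })
    })
    lib <- c(lib, decoys)
  }
  lib
}
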