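#' Minimum-free-energy provider adapter
#'
#' RNA secondary-structure prediction is delegated to an external folding
#' engine behind a provider object, so its absence is a detectable
#' condition rather than a silent zero. [vienna_mfe_provider()] adapts
#' the ViennaRNA `RNAfold` command-line tool when it is on the PATH.
#'
#' @param fun Function mapping one CDS string to an MFE in kcal/mol
#'   (<= 0 for foldable sequences).
#' @param available Logical availability flag.
#' @param name Human-readable provider name.
#' @return Object of class `mfe_provider`.
#' @export
mfe_provider <- function(fun, available = TRUE, name = "custom") {
  cl_assert(is.function(fun), "fun must be a function", "codonlm_bad_input")
  structure(list(fun = fun, available = isTRUE(available), name = name),
            class = "mfe_provider")
}

#' @rdname mfe_provider
#' @param command Name or path of the RNAfold executable.
#' @export
vienna_mfe_provider <- function(command = "RNAfold") {
  path <- Sys.which(command)
  fun <- function(cds) {
    out <- suppressWarnings(system2(path, args = "--noPS", input = cds,
                                    stdout = TRUE, stderr = FALSE))
    m <- regmatches(out, regexpr("\\(\\s*-?[0-9.]+\\s*\\)\\s*$", out))
    m <- m[lengths(regmatches(m, gregexpr("[0-9]", m))) > 0]
    if (length(m) == 0L)
      cl_stop("could not parse RNAfold output", "codonlm_mfe_error")
    as.numeric(gsub("[() ]", "", m[[length(m)]]))
  }
  mfe_provider(fun, available = nzchar(path),
               name = paste0("ViennaRNA RNAfold (", command, ")"))
}

#' @rdname mfe_provider
#' @param provider An `mfe_provider`.
#' @export
mfe_available <- function(provider) {
  inherits(provider, "mfe_provider") && isTRUE(provider$available)
}

#' Compute MFE for a set of sequences
#'
#' Per-sequence provider failures are surfaced as warnings and `NA`
#' values, never as a fatal error.
#'
#' @param provider An [mfe_provider()].
#' @param cds Character vector of sequences.
#' @return Numeric vector of MFE values (kcal/mol), `NA` on failure.
#' @export
compute_mfe <- function(provider, cds) {
  cl_assert(mfe_available(provider), "MFE provider is not available",
            "codonlm_no_mfe_provider")
  vapply(cds, function(s) {
    tryCatch(provider$fun(s), error = function(e) {
      warning("MFE failed for a sequence: ", conditionMessage(e))
      NA_real_
    })
  }, 0, USE.NAMES = FALSE)
}
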