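#' Enumerate the full stimulus set for a panel of odorants
#'
#' Stimuli are encoded as bitmasks over odorant indices: bit \code{i}
#' (value \code{2^(i-1)}) is set when odorant \code{i} is present. For a
#' panel of \code{n} odorants the full set contains every nonempty subset,
#' i.e. \code{2^n - 1} stimuli; with the standard 4-odorant panel that is
#' 15 stimuli (4 singles, 6 pairs, 4 triplets, 1 quadruple mixture).
#'
#' @param nOdorants Number of odorants in the panel.
#' @return Integer vector of stimulus bitmasks, sorted by mixture size and
#'   then by bitmask value.
#' @examples
#' stimulusSet(4)
#' @export
stimulusSet <- function(nOdorants) {
  stopifnot(is.numeric(nOdorants), length(nOdorants) == 1L, nOdorants >= 1)
  masks <- seq_len(2L^as.integer(nOdorants) - 1L)
  masks[order(mixtureSize(masks), masks)]
}

#' Number of components in a stimulus
#'
#' @param bitmask Integer stimulus bitmask(s).
#' @return Integer vector: the number of set bits (odorants) per stimulus.
#' @examples
#' mixtureSize(c(1L, 3L, 15L))
#' @export
mixtureSize <- function(bitmask) {
  vapply(as.integer(bitmask),
         function(m) sum(bitwAnd(m, bitwShiftL(1L, 0:30)) != 0L),
         integer(1))
}

#' Odorants present in a stimulus
#'
#' @param bitmask A single stimulus bitmask.
#' @return Integer vector of 1-based odorant indices present in the stimulus.
#' @examples
#' stimulusComponents(11L) # odorants 1, 2 and 4
#' @export
stimulusComponents <- function(bitmask) {
  bitmask <- as.integer(bitmask)
  stopifnot(length(bitmask) == 1L, bitmask >= 1L)
  which(bitwAnd(bitmask, bitwShiftL(1L, 0:30)) != 0L)
}

#' Human-readable stimulus label
#'
#' @param bitmask Integer stimulus bitmask(s).
#' @return Character labels such as \code{"od1+od3"}.
#' @export
stimulusLabel <- function(bitmask) {
  vapply(as.integer(bitmask), function(m) {
    paste0("od", stimulusComponents(m), collapse = "+")
  }, character(1))
}

## Derive a stream of child seeds from one master seed, keeping every value
## a valid 32-bit R integer. Used so each pipeline stage and classifier
## iteration has its own reproducible stream.
childSeeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  ## arithmetic in double to avoid 32-bit overflow before the modulus
  as.integer((as.numeric(seed) + 1000003 * as.numeric(seq_len(n))) %%
               2147483647)
}

## Half-open window membership [lo, hi) used for every spike-count window
## in the package, so a boundary spike is never counted twice.
inWindow <- function(t, lo, hi) t >= lo & t < hi
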