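DNA_BASES <- c("A", "C", "G", "T")

#' Derive a stage-specific sub-seed from the run seed
#'
#' Each pipeline stage draws from its own stream so that adding or
#' reordering stages never perturbs the output of earlier stages.
#' The derived seed is kept below 2^31 - 1.
#'
#' @param seed integer run seed.
#' @param stage character stage label.
#' @return An integer seed.
#' @keywords internal
stageSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

#' Uniform random DNA string
#' @param n length in bases.
#' @return A single character string over ACGT.
#' @keywords internal
randomDnaString <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# substitute bases at `pos` (1-based) of a raw vector holding DNA text with
# random different bases; returns list(raw, ref, alt)
.substituteBases <- function(seqRaw, pos) {
  if (length(pos) == 0L) {
    return(list(raw = seqRaw, ref = character(), alt = character()))
  }
  ref <- rawToChar(seqRaw[pos], multiple = TRUE)
  alts <- rbind(A = c("C", "G", "T"), C = c("A", "G", "T"),
                G = c("A", "C", "T"), T = c("A", "C", "G"))
  pick <- sample.int(3L, length(pos), replace = TRUE)
  alt <- alts[cbind(match(ref, rownames(alts)), pick)]
  seqRaw[pos] <- charToRaw(paste(alt, collapse = ""))
  list(raw = seqRaw, ref = ref, alt = alt)
}

# Jukes-Cantor marginal: probability a site differs after accumulating an
# expected K substitutions per site
.jcDiffProb <- function(k) 0.75 * (1 - exp(-4 * k / 3))

.isWholeNumber <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && abs(x - round(x)) < 1e-8
}

.assertScalarIn <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi) {
    stop(sprintf("'%s' must be a single finite number in [%s, %s]",
                 name, format(lo), format(hi)), call. = FALSE)
  }
  invisible(x)
}

# coerce character / XString / length-1 XStringSet to a plain character string
.asSeqChar <- function(x) {
  if (is.character(x)) {
    if (length(x) != 1L) stop("expected a single sequence", call. = FALSE)
    return(toupper(x))
  }
  as.character(x)
}
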