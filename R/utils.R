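# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded operations do not
#' disturb the global stream.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      stats::runif(1L)
    }
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Stage-local seed derived deterministically from the run seed, kept inside
# 32-bit integer range.
derive_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

#' Reverse complement of DNA strings
#' @noRd
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Extract read sequences from a genome string. `pos` is the 0-based 5' end
# of the read; forward reads run rightward, reverse reads leftward and are
# reverse-complemented. All coordinates must be inside the genome.
extract_read_seq <- function(genome, pos, strand, len) {
  n <- length(pos)
  if (n == 0L) return(character(0))
  L <- nchar(genome)
  fwd <- strand == "+"
  start1 <- ifelse(fwd, pos + 1L, pos - len + 2L)
  end1 <- ifelse(fwd, pos + len, pos + 1L)
  if (any(start1 < 1L) || any(end1 > L)) {
    stop("read extends beyond the genome edge")
  }
  out <- substring(genome, start1, end1)
  if (any(!fwd)) out[!fwd] <- revcomp(out[!fwd])
  out
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("'%s' must be a single probability in [0, 1]", name))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
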