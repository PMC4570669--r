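#' Enumerate the all-against-all comparison schedule
#'
#' Index vectors of every unordered pair over `n` items, the schedule an
#' all-vs-all structural alignment run works through. For the 4,098-domain
#' dataset scale this enumerates all C(4098, 2) = 8,394,753 pairs in memory.
#'
#' @param n number of items (or a vector of identifiers, whose length is used).
#' @return list with integer vectors `i`, `j` (i < j) and count `n_pairs`.
#' @export
pair_schedule <- function(n) {
  if (length(n) > 1L) n <- length(n)
  n <- as.integer(n)
  stopifnot(n >= 0)
  if (n < 2L) return(list(i = integer(0), j = integer(0), n_pairs = 0L))
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- sequence((n - 1L):1L, from = 2L:n)
  list(i = i, j = j, n_pairs = length(i))
}

# canonical unordered-pair key
pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
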