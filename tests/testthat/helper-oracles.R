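# Independent brute-force oracles: deliberately naive loops, kept free of
# the package's own scanning/counting code paths.

random_dna <- function(n, probs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

random_at_rich <- function(n) {
  random_dna(n, c(A = 0.45, C = 0.04, G = 0.03, T = 0.48))
}

# character histogram by plain looping
oracle_base_tally <- function(seq) {
  x <- strsplit(toupper(seq), "")[[1]]
  out <- c(A = 0L, C = 0L, G = 0L, T = 0L, other = 0L)
  for (ch in x) {
    if (ch %in% c("A", "C", "G", "T")) out[ch] <- out[ch] + 1L
    else out["other"] <- out["other"] + 1L
  }
  out
}

# all (overlapping) motif occurrences, N wildcard, O(nm) scan
oracle_motif_scan <- function(seq, motif) {
  s <- strsplit(toupper(seq), "")[[1]]
  m <- strsplit(toupper(motif), "")[[1]]
  starts <- integer(0)
  if (length(m) > length(s)) return(starts)
  for (i in 1:(length(s) - length(m) + 1)) {
    ok <- TRUE
    for (j in seq_along(m)) {
      if (m[j] != "N" && s[i + j - 1] != m[j]) { ok <- FALSE; break }
    }
    if (ok) starts <- c(starts, i)
  }
  starts
}

# maximal homopolymer runs >= min_len as a start/length data.frame
oracle_runs <- function(seq, base, min_len) {
  s <- strsplit(toupper(seq), "")[[1]]
  out <- data.frame(start = integer(0), len = integer(0))
  i <- 1
  while (i <= length(s)) {
    if (s[i] == base) {
      j <- i
      while (j < length(s) && s[j + 1] == base) j <- j + 1
      if (j - i + 1 >= min_len) out <- rbind(out, data.frame(start = i, len = j - i + 1))
      i <- j + 1
    } else i <- i + 1
  }
  out
}

# maximal unit arrays (left-maximal on whole units, partial counted in end)
oracle_microsat <- function(seq, unit, min_copies) {
  s <- toupper(seq); u <- nchar(unit); n <- nchar(s)
  out <- data.frame(start = integer(0), end = integer(0), copies = integer(0))
  for (i in seq_len(max(n - u + 1, 0))) {
    if (substr(s, i, i + u - 1) != unit) next
    if (i - u >= 1 && substr(s, i - u, i - 1) == unit) next # not left-maximal
    k <- 1
    while (i + (k + 1) * u - 1 <= n &&
           substr(s, i + k * u, i + (k + 1) * u - 1) == unit) k <- k + 1
    if (k < min_copies) next
    p <- 0
    while (p < u && i + k * u + p <= n &&
           substr(s, i + k * u + p, i + k * u + p) == substr(unit, p + 1, p + 1)) {
      p <- p + 1
    }
    out <- rbind(out, data.frame(start = i, end = i + k * u + p - 1, copies = k))
  }
  out
}

oracle_smallest_period <- function(s) {
  x <- strsplit(s, "")[[1]]
  n <- length(x)
  for (p in 1:(n - 1)) {
    periodic <- TRUE
    for (i in 1:(n - p)) if (x[i] != x[i + p]) { periodic <- FALSE; break }
    if (periodic) return(p)
  }
  n
}

# maximal tandem arrays reported at their smallest period >= min_unit
oracle_tandem <- function(seq, min_unit, min_copies) {
  s <- toupper(seq); n <- nchar(s)
  found <- list()
  for (u in min_unit:max(min_unit, n %/% min_copies)) {
    if (2 * u > n) break
    for (i in 1:(n - 2 * u + 1)) {
      # maximal: position i must start the array (mismatch at i-1 vs i-1+u)
      if (i > 1 && substr(s, i - 1, i - 1) == substr(s, i - 1 + u, i - 1 + u)) next
      m <- 0
      while (i + u + m <= n &&
             substr(s, i + m, i + m) == substr(s, i + u + m, i + u + m)) m <- m + 1
      total <- u + m
      if (total %/% u < min_copies) next
      span <- substr(s, i, i + total - 1)
      if (oracle_smallest_period(span) != u) next
      found[[length(found) + 1]] <-
        data.frame(start = i, end = i + total - 1, unit = substr(s, i, i + u - 1),
                   copies = total %/% u)
    }
  }
  if (length(found) == 0) {
    return(data.frame(start = integer(0), end = integer(0),
                      unit = character(0), copies = integer(0)))
  }
  out <- do.call(rbind, found)
  out[order(out$start, out$end), , drop = FALSE]
}

# minimum number of genes to delete from both orders to make them equal,
# by exhaustive subset search (for small gene sets)
oracle_min_moved <- function(a, b) {
  stopifnot(setequal(a, b))
  for (k in 0:length(a)) {
    subsets <- utils::combn(a, k, simplify = FALSE)
    for (s in subsets) {
      if (identical(a[!a %in% s], b[!b %in% s])) return(k)
    }
  }
  length(a)
}

# a small fully-annotated circular genome built by hand for IO tests
toy_annotation <- function() {
  tibble::tibble(
    gene = c("geneA", "trnX", "geneB", "control_region"),
    category = c("PCG", "tRNA", "PCG", "control"),
    strand = c("F", "R", "F", "F"),
    start = c(1L, 31L, 46L, 76L),
    end = c(30L, 45L, 75L, 90L),
    anticodon = c(NA, "CAT", NA, NA),
    start_codon = c("ATG", NA, "ATT", NA),
    stop_codon = c("TAA", NA, "TAA", NA)
  )
}
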