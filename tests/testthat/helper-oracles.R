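# Independent oracles used by the tests. These deliberately avoid the
# package's own code paths (pure R, base string ops) so that agreement is
# evidence, not tautology.

rnd_protein <- function(n) {
  paste0(sample(genoplast:::AA20, n, replace = TRUE), collapse = "")
}

rnd_dna <- function(n, gc = 0.5) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
         collapse = "")
}

revcomp_chr <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

# ---- brute-force optimal alignment scores (memoised recursion over
# alignment moves with affine gap states; formulated independently of the
# package's iterative Gotoh kernel) ----

bf_global_score <- function(a, b, scheme) {
  mat <- scheme$matrix
  open <- scheme$gap_open
  ext <- scheme$gap_extend
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  m <- length(ca)
  n <- length(cb)
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j, prev) {
    key <- paste(i, j, prev)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    if (i > m && j > n) return(0)
    best <- -Inf
    if (i <= m && j <= n)
      best <- max(best, mat[ca[i], cb[j]] + rec(i + 1, j + 1, "M"))
    if (i <= m)
      best <- max(best, -(if (prev == "X") ext else open + ext) + rec(i + 1, j, "X"))
    if (j <= n)
      best <- max(best, -(if (prev == "Y") ext else open + ext) + rec(i, j + 1, "Y"))
    memo[[key]] <- best
    best
  }
  rec(1, 1, "S")
}

# local score = best global score over all substring pairs (floor 0)
bf_local_score <- function(a, b, scheme) {
  m <- nchar(a)
  n <- nchar(b)
  best <- 0
  for (i1 in 1:m) for (i2 in i1:m) {
    sa <- substr(a, i1, i2)
    for (j1 in 1:n) for (j2 in j1:n) {
      best <- max(best, bf_global_score(sa, substr(b, j1, j2), scheme))
    }
  }
  best
}

# ---- quadratic maximal-unique-match oracle ----

# every diagonal of the (a, b) comparison is scanned with vectorised
# character equality; runs >= min_len are maximal matches, then uniqueness
# of the match string (both strands) is checked with gregexpr
oracle_mums <- function(a, b, min_len = 20) {
  na <- nchar(a)
  nb <- nchar(b)
  va <- utf8ToInt(a)
  rows <- list()
  for (orient in c("forward", "reverse")) {
    btxt <- if (orient == "forward") b else revcomp_chr(b)
    vb <- utf8ToInt(btxt)
    for (d in (-(na - 1)):(nb - 1)) {
      ia <- max(0, -d)
      ib <- ia + d
      len <- min(na - ia, nb - ib)
      if (len < min_len) next
      eq <- va[(ia + 1):(ia + len)] == vb[(ib + 1):(ib + len)]
      r <- rle(eq)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths
      for (k in which(r$values & r$lengths >= min_len)) {
        s0 <- ia + starts[k]
        t0 <- ib + starts[k]
        L <- r$lengths[k]
        sb <- if (orient == "forward") t0 else nb - (t0 + L)
        rows[[length(rows) + 1]] <- data.frame(
          start_a = s0, start_b = sb, length = L, orientation = orient,
          stringsAsFactors = FALSE)
      }
    }
  }
  m <- do.call(rbind, rows)
  if (is.null(m)) {
    return(data.frame(start_a = integer(), start_b = integer(),
                      length = integer(), orientation = character(),
                      stringsAsFactors = FALSE))
  }
  n_occ <- function(s, txt) {
    hits <- gregexpr(s, txt, fixed = TRUE)[[1]]
    n1 <- if (hits[1] == -1) 0L else length(hits)
    rs <- revcomp_chr(s)
    hits2 <- gregexpr(rs, txt, fixed = TRUE)[[1]]
    n1 + (if (hits2[1] == -1) 0L else length(hits2))
  }
  keep <- vapply(seq_len(nrow(m)), function(k) {
    s <- substr(a, m$start_a[k] + 1, m$start_a[k] + m$length[k])
    n_occ(s, a) == 1 && n_occ(s, b) == 1
  }, logical(1))
  m <- m[keep, , drop = FALSE]
  m <- m[order(m$start_a, m$start_b), , drop = FALSE]
  rownames(m) <- NULL
  m
}

# a 20 kb genome pair with copied, inverted, mutated and duplicated
# segments so the anchor set is non-trivial
structured_pair <- function(seed = 1) {
  set.seed(seed)
  a <- rnd_dna(20000)
  mut <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    pos <- sample(length(ch), k)
    ch[pos] <- vapply(ch[pos], function(x)
      sample(setdiff(c("A", "C", "G", "T"), x), 1), "")
    paste(ch, collapse = "")
  }
  dup <- substr(a, 18001, 18400) # appears twice in b -> never unique
  b <- paste0(
    substr(a, 2001, 6000),
    rnd_dna(1500),
    revcomp_chr(substr(a, 8001, 11000)),
    dup, rnd_dna(300), dup,
    mut(substr(a, 12001, 16000), 40),
    rnd_dna(1000))
  list(a = a, b = b)
}

# mirror a one-replicon genome: reverse-complement sequence, flip features
mirror_genome <- function(genome) {
  r <- genome$replicons[[1]]
  len <- nchar(r$sequence)
  feats <- lapply(r$features, function(f) {
    s <- len - f$end
    e <- len - f$start
    f$start <- as.integer(s)
    f$end <- as.integer(e)
    f$strand <- if (f$strand == "+") "-" else "+"
    f
  })
  annotated_genome(genome$genome_id, genome$organism,
                   list(replicon(r$name, genoplast::revcomp(r$sequence),
                                 r$topology, r$role, feats)))
}
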