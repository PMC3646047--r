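# Data model for annotated genomes. Internal coordinates are 0-based
# half-open; GenBank flat-file I/O converts to/from the native 1-based
# inclusive convention. Features are typed (CDS, pseudogene, rRNA, tRNA),
# stranded, and sorted by start within each replicon.

FEATURE_KINDS <- c("CDS", "pseudogene", "rRNA", "tRNA")

#' Construct a genome feature
#'
#' @param kind one of CDS, pseudogene, rRNA, tRNA
#' @param start,end 0-based half-open interval on the replicon
#' @param strand "+" or "-"
#' @param locus_tag unique locus identifier
#' @param product free-text product description
#' @param te_family optional transposable-element family label (e.g. "IS3")
#' @return a `feature` object (named list)
#' @export
feature <- function(kind, start, end, strand, locus_tag,
                    product = "", te_family = NA_character_) {
  kind <- match.arg(kind, FEATURE_KINDS)
  stopifnot(start >= 0, start < end, strand %in% c("+", "-"))
  structure(list(kind = kind, start = as.integer(start), end = as.integer(end),
                 strand = strand, locus_tag = locus_tag, product = product,
                 te_family = te_family),
            class = "feature")
}

#' Construct a replicon
#'
#' @param name replicon name (unique within a genome)
#' @param sequence nucleotide string over A,C,G,T,N
#' @param topology "circular" or "linear"
#' @param role "chromosome" or "plasmid"
#' @param features list of [feature()] objects; stored sorted by start
#' @return a `replicon` object
#' @export
replicon <- function(name, sequence, topology = c("circular", "linear"),
                     role = c("chromosome", "plasmid"), features = list()) {
  topology <- match.arg(topology)
  role <- match.arg(role)
  sequence <- toupper(sequence)
  stopifnot(nchar(sequence) > 0)
  if (grepl("[^ACGTN]", sequence)) stopf("replicon %s: non-ACGTN characters", name)
  len <- nchar(sequence)
  for (f in features) {
    if (f$end > len) stopf("feature %s exceeds replicon %s length", f$locus_tag, name)
  }
  ord <- order(vapply(features, function(f) f$start, integer(1)))
  structure(list(name = name, sequence = sequence, topology = topology,
                 role = role, features = features[ord]),
            class = "replicon")
}

#' Construct an annotated genome
#'
#' @param genome_id short identifier
#' @param organism organism name
#' @param replicons list of [replicon()] objects
#' @return an `annotated_genome` object
#' @export
annotated_genome <- function(genome_id, organism, replicons) {
  stopifnot(length(replicons) >= 1)
  nm <- vapply(replicons, function(r) r$name, character(1))
  if (anyDuplicated(nm)) stopf("replicon names must be unique")
  tags <- unlist(lapply(replicons, function(r)
    vapply(r$features, function(f) f$locus_tag, character(1))))
  if (anyDuplicated(tags)) stopf("locus_tags must be unique within a genome")
  structure(list(genome_id = genome_id, organism = organism,
                 replicons = stats::setNames(replicons, nm)),
            class = "annotated_genome")
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf("<annotated_genome> %s (%s): %d replicon(s), %d features, %.2f Mb\n",
              x$genome_id, x$organism, length(x$replicons),
              nrow(feature_table(x)), genome_length(x) / 1e6))
  invisible(x)
}

#' Total genome length in bp
#' @param genome an `annotated_genome`
#' @return integer length
#' @export
genome_length <- function(genome) {
  sum(vapply(genome$replicons, function(r) nchar(r$sequence), integer(1)))
}

#' Flat table of all features of a genome
#' @param genome an `annotated_genome`
#' @return data.frame with replicon, kind, start, end, strand, locus_tag,
#'   product, te_family (0-based half-open coordinates)
#' @export
feature_table <- function(genome) {
  rows <- lapply(genome$replicons, function(r) {
    if (length(r$features) == 0) return(NULL)
    data.frame(
      replicon = r$name,
      kind = vapply(r$features, `[[`, character(1), "kind"),
      start = vapply(r$features, `[[`, integer(1), "start"),
      end = vapply(r$features, `[[`, integer(1), "end"),
      strand = vapply(r$features, `[[`, character(1), "strand"),
      locus_tag = vapply(r$features, `[[`, character(1), "locus_tag"),
      product = vapply(r$features, `[[`, character(1), "product"),
      te_family = vapply(r$features, `[[`, character(1), "te_family"),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(replicon = character(), kind = character(),
                      start = integer(), end = integer(), strand = character(),
                      locus_tag = character(), product = character(),
                      te_family = character(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

# ---- GenBank flat-file I/O ---------------------------------------------

# parse a GenBank location string into (start0, end0, strand); join/complement
# resolved to outermost bounds. Returns NULL on malformed input.
.parse_location <- function(loc) {
  strand <- "+"
  x <- gsub("[<>]", "", gsub("[[:space:]]", "", loc))
  if (grepl("^complement\\(", x)) {
    strand <- "-"
    x <- sub("^complement\\((.*)\\)$", "\\1", x)
  }
  if (grepl("^join\\(", x) || grepl("^order\\(", x)) {
    x <- sub("^(join|order)\\((.*)\\)$", "\\2", x)
  }
  # inner complement (rare): flips strand
  if (grepl("complement\\(", x)) {
    strand <- if (strand == "+") "-" else "+"
    x <- gsub("complement\\(|\\)", "", x)
  }
  parts <- strsplit(x, ",", fixed = TRUE)[[1]]
  bounds <- suppressWarnings(lapply(parts, function(p) {
    nums <- as.integer(strsplit(p, "\\.\\.")[[1]])
    if (anyNA(nums) || length(nums) < 1 || length(nums) > 2) return(NULL)
    range(nums)
  }))
  if (any(vapply(bounds, is.null, logical(1))) || length(bounds) == 0) return(NULL)
  lo <- min(vapply(bounds, min, numeric(1)))
  hi <- max(vapply(bounds, max, numeric(1)))
  list(start = as.integer(lo - 1L), end = as.integer(hi), strand = strand)
}

#' Read a GenBank flat file into an annotated genome
#'
#' Handles multi-record files (one replicon per LOCUS). CDS features without
#' a `/pseudo` qualifier become kind CDS; CDS or gene features with
#' `/pseudo` become pseudogenes; rRNA/tRNA map to their kinds. 1-based
#' inclusive locations (including `join(...)` and `complement(...)`) are
#' converted to 0-based half-open with outermost bounds. A
#' `/mobile_element_type` qualifier of the form "insertion sequence:ISx" is
#' stored as the feature's TE family.
#'
#' @param path GenBank flat file
#' @param genome_id,organism identifiers; defaults derived from the file
#' @return an `annotated_genome`
#' @export
read_genbank <- function(path, genome_id = NULL, organism = NULL) {
  lines <- readLines(path, warn = FALSE)
  recs <- split(lines, cumsum(c(TRUE, grepl("^//\\s*$", head(lines, -1)))))
  recs <- Filter(function(r) any(grepl("^LOCUS", r)), recs)
  if (length(recs) == 0) stopf("%s: no LOCUS record found", path)
  replicons <- lapply(recs, .parse_genbank_record)
  org <- organism %||% attr(replicons[[1]], "organism") %||% "unknown organism"
  gid <- genome_id %||% sub("\\.[^.]*$", "", basename(path))
  annotated_genome(gid, org, lapply(replicons, identity))
}

.parse_genbank_record <- function(rl) {
  locus_line <- rl[grepl("^LOCUS", rl)][1]
  toks <- strsplit(trimws(locus_line), "\\s+")[[1]]
  name <- toks[2]
  topology <- if (any(toks == "circular")) "circular" else "linear"
  org_line <- rl[grepl("^\\s{0,2}(SOURCE|  ORGANISM)", rl)]
  organism <- if (length(org_line)) trimws(sub("^\\s*(SOURCE|ORGANISM)\\s*", "", org_line[1])) else NULL
  def_line <- rl[grepl("^DEFINITION", rl)]
  role <- if (length(def_line) && grepl("plasmid", def_line[1], ignore.case = TRUE))
    "plasmid" else "chromosome"

  io <- grep("^ORIGIN", rl)
  if (length(io) == 0) stopf("record %s: missing ORIGIN sequence block", name)
  seq_lines <- rl[(io[1] + 1):length(rl)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", cc(seq_lines)))
  if (nchar(sequence) == 0) stopf("record %s: empty sequence", name)

  ifeat <- grep("^FEATURES", rl)
  features <- list()
  if (length(ifeat)) {
    ft <- rl[(ifeat[1] + 1):(io[1] - 1)]
    # feature starts: key at column 6 (5 spaces + key)
    starts <- grep("^ {5}\\S", ft)
    for (s in seq_along(starts)) {
      from <- starts[s]
      to <- if (s < length(starts)) starts[s + 1] - 1 else length(ft)
      block <- ft[from:to]
      key <- sub("^\\s+", "", sub("^ {5}(\\S+).*$", "\\1", block[1]))
      if (!key %in% c("CDS", "gene", "rRNA", "tRNA")) next
      # location may wrap lines until first qualifier
      qstart <- grep("^\\s{10,}/", block)
      locend <- if (length(qstart)) qstart[1] - 1 else length(block)
      loc <- cc(trimws(c(sub("^ {5}\\S+\\s*", "", block[1]),
                         if (locend >= 2) trimws(block[2:locend]) else character(0))))
      quals <- .parse_qualifiers(block[if (length(qstart)) qstart[1]:length(block) else integer(0)])
      pseudo <- "pseudo" %in% names(quals) || "pseudogene" %in% names(quals)
      if (key == "gene" && !pseudo) next  # plain gene features mirror CDS
      pl <- .parse_location(loc)
      tag <- quals[["locus_tag"]] %||% sprintf("%s_f%04d", name, s)
      if (is.null(pl)) stopf("record %s: malformed location for %s: '%s'", name, tag, loc)
      kind <- if (key %in% c("CDS", "gene")) (if (pseudo) "pseudogene" else "CDS") else key
      tef <- NA_character_
      met <- quals[["mobile_element_type"]]
      if (!is.null(met)) tef <- sub("^.*:", "", met)
      f <- feature(kind, pl$start, pl$end, pl$strand, tag,
                   product = quals[["product"]] %||% "", te_family = tef)
      f$translation <- quals[["translation"]]
      features <- c(features, list(f))
    }
    # a pseudo 'gene' and a CDS may describe the same locus: prefer one entry
    tags <- vapply(features, `[[`, character(1), "locus_tag")
    features <- features[!duplicated(tags)]
  }
  r <- replicon(name, sequence, topology, role, features)
  attr(r, "organism") <- organism
  r
}

.parse_qualifiers <- function(lines) {
  if (length(lines) == 0) return(list())
  txt <- trimws(lines)
  qi <- grep("^/", txt)
  quals <- list()
  for (k in seq_along(qi)) {
    from <- qi[k]
    to <- if (k < length(qi)) qi[k + 1] - 1 else length(txt)
    piece <- cc(txt[from:to])
    m <- regmatches(piece, regexec("^/([A-Za-z_]+)(=(.*))?$", piece))[[1]]
    if (length(m) == 0) next
    key <- m[2]
    val <- if (nchar(m[4])) gsub("^\"|\"$", "", m[4]) else TRUE
    quals[[key]] <- val
  }
  quals
}

#' Write an annotated genome as a GenBank flat file
#'
#' Emits one LOCUS record per replicon with CDS/rRNA/tRNA features (pseudo
#' CDS carry `/pseudo`), 1-based inclusive locations, and the full ORIGIN
#' block. Round-trips through [read_genbank()].
#'
#' @param genome an `annotated_genome`
#' @param path output path
#' @return invisibly, `path`
#' @export
write_genbank <- function(genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in genome$replicons) {
    len <- nchar(r$sequence)
    writeLines(sprintf("LOCUS       %s %d bp    DNA     %s   BCT",
                       r$name, len, r$topology), con)
    writeLines(sprintf("DEFINITION  %s %s%s.", genome$organism, r$name,
                       if (r$role == "plasmid") " plasmid" else ""), con)
    writeLines(sprintf("SOURCE      %s", genome$organism), con)
    writeLines("FEATURES             Location/Qualifiers", con)
    writeLines(sprintf("     source          1..%d", len), con)
    for (f in r$features) {
      loc <- sprintf("%d..%d", f$start + 1L, f$end)
      if (f$strand == "-") loc <- sprintf("complement(%s)", loc)
      key <- switch(f$kind, CDS = "CDS", pseudogene = "CDS",
                    rRNA = "rRNA", tRNA = "tRNA")
      writeLines(sprintf("     %-16s%s", key, loc), con)
      writeLines(sprintf("                     /locus_tag=\"%s\"", f$locus_tag), con)
      if (nzchar(f$product))
        writeLines(sprintf("                     /product=\"%s\"", f$product), con)
      if (f$kind == "pseudogene")
        writeLines("                     /pseudo", con)
      if (!is.na(f$te_family))
        writeLines(sprintf("                     /mobile_element_type=\"insertion sequence:%s\"",
                           f$te_family), con)
    }
    writeLines("ORIGIN", con)
    pos <- seq(1, len, by = 60)
    for (p in pos) {
      starts <- seq(p, min(p + 59, len), by = 10)
      block <- substring(r$sequence, starts, pmin(starts + 9, len))
      writeLines(sprintf("%9d %s", p, tolower(paste(block, collapse = " "))), con)
    }
    writeLines("//", con)
  }
  invisible(path)
}

# ---- proteome / statistics ---------------------------------------------

#' Extract the proteome of a genome
#'
#' One protein record per non-pseudo CDS. The stored `/translation` is used
#' when present; otherwise the CDS span is translated with the bacterial
#' code (reverse strand features are reverse-complemented first) and the
#' trailing stop is removed. CDS with internal stops are skipped with a
#' warning and counted in the `skipped` attribute.
#'
#' @param genome an `annotated_genome`
#' @return data.frame (protein_id, genome_id, replicon, locus_tag, sequence)
#' @export
extract_proteome <- function(genome) {
  tag <- repl <- spans <- given <- character(0)
  strand <- character(0)
  for (r in genome$replicons) {
    for (f in r$features) {
      if (f$kind != "CDS") next
      tag <- c(tag, f$locus_tag)
      repl <- c(repl, r$name)
      given <- c(given, f$translation %||% NA_character_)
      strand <- c(strand, f$strand)
      spans <- c(spans, substr(r$sequence, f$start + 1L, f$end))
    }
  }
  skipped <- 0L
  if (length(tag)) {
    need <- is.na(given)
    if (any(need)) {
      nt <- spans[need]
      minus <- strand[need] == "-"
      x <- Biostrings::DNAStringSet(nt)
      if (any(minus)) x[minus] <- Biostrings::reverseComplement(x[minus])
      w <- Biostrings::width(x)
      x <- Biostrings::subseq(x, 1L, w - w %% 3L)
      aa <- as.character(suppressWarnings(
        Biostrings::translate(x, if.fuzzy.codon = "X")))
      given[need] <- aa
    }
    internal_stop <- grepl("\\*", sub("\\*$", "", given))
    if (any(internal_stop)) {
      warnf("internal stop in non-pseudo CDS, skipped: %s",
            paste(tag[internal_stop], collapse = ","))
      skipped <- sum(internal_stop)
    }
    keep <- !internal_stop
    out <- data.frame(protein_id = tag[keep],
                      genome_id = rep(genome$genome_id, sum(keep)),
                      replicon = repl[keep], locus_tag = tag[keep],
                      sequence = sub("\\*$", "", given[keep]),
                      stringsAsFactors = FALSE)
  } else {
    out <- data.frame(protein_id = character(), genome_id = character(),
                      replicon = character(), locus_tag = character(),
                      sequence = character(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

# translate an in-frame CDS nucleotide string (bacterial code), keep stops as *
translate_cds <- function(nt) {
  n <- nchar(nt) - nchar(nt) %% 3
  if (n < 3) return(NULL)
  as.character(suppressWarnings(
    Biostrings::translate(Biostrings::DNAString(substr(nt, 1, n)),
                          if.fuzzy.codon = "X")))
}

#' GC content of a genome
#'
#' 100 * (G+C) / (A+C+G+T) over all replicons concatenated; N excluded from
#' the denominator.
#'
#' @param genome an `annotated_genome` (or a single nucleotide string)
#' @param rounded round half away from zero to the nearest integer
#'   (genome-table reporting style)
#' @return percentage in `[0, 100]`
#' @export
gc_content <- function(genome, rounded = FALSE) {
  seqs <- if (inherits(genome, "annotated_genome"))
    vapply(genome$replicons, `[[`, character(1), "sequence") else genome
  x <- Biostrings::DNAStringSet(seqs)
  fr <- colSums(Biostrings::letterFrequency(x, c("A", "C", "G", "T")))
  denom <- sum(fr)
  if (denom == 0) stopf("gc_content undefined: no A/C/G/T bases")
  pct <- 100 * (fr[["G"]] + fr[["C"]]) / denom
  if (rounded) floor(pct + 0.5) else pct
}

#' Whole-genome summary statistics
#'
#' Mirrors a genome-table row: GC percent, size in Mb, protein-coding /
#' pseudogene / RNA gene counts, TE-associated gene count and TE density
#' per Mb. RNA genes are rRNA + tRNA features only.
#'
#' @param genome an `annotated_genome`
#' @param te_census optional TE census from [te_census()]; without it the
#'   TE columns fall back to the features' own `te_family` annotations
#' @return a `genome_summary` (named list)
#' @export
summarize_genome <- function(genome, te_census = NULL) {
  ft <- feature_table(genome)
  mb <- genome_length(genome) / 1e6
  if (!is.null(te_census)) {
    n_te <- te_census$total_genes
  } else {
    n_te <- sum(ft$kind == "CDS" & !is.na(ft$te_family))
  }
  structure(list(
    genome_id = genome$genome_id,
    gc_percent = gc_content(genome),
    gc_percent_rounded = gc_content(genome, rounded = TRUE),
    length_mb = mb,
    n_protein_coding = sum(ft$kind == "CDS"),
    n_pseudogenes = sum(ft$kind == "pseudogene"),
    n_rna_genes = sum(ft$kind %in% c("rRNA", "tRNA")),
    n_te_genes = n_te,
    te_per_mb = n_te / mb
  ), class = "genome_summary")
}

#' @export
print.genome_summary <- function(x, ...) {
  cat(sprintf(
    "<genome_summary> %s: GC %d%%, %.2f Mb, %d CDS, %d pseudogenes, %d RNA genes, %d TE genes (%.1f/Mb)\n",
    x$genome_id, x$gc_percent_rounded, x$length_mb, x$n_protein_coding,
    x$n_pseudogenes, x$n_rna_genes, x$n_te_genes, x$te_per_mb))
  invisible(x)
}

#' Proteome as a named character vector
#' @param genome an `annotated_genome`
#' @return named character vector locus_tag -> protein sequence
#' @export
proteome_seqs <- function(genome) {
  p <- extract_proteome(genome)
  stats::setNames(p$sequence, p$protein_id)
}
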