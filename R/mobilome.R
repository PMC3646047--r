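# Transposable-element census against a labelled IS-family reference
# library, windowed GC deviation profiles, and composite calling of regions
# of enhanced genome plasticity (RGPs): genome intervals supported by at
# least 2 of 3 independent horizontal-transfer indicators (atypical GC,
# ortholog poverty against close relatives, TE clustering). Plasmids are
# emitted whole as RGPs.

#' TE reference library
#'
#' @param seqs named character vector of transposase/mobility protein
#'   sequences
#' @param family IS-family label per record (e.g. "IS3", "IS5", "IS110")
#' @param subgroup optional subgroup label per record
#' @return a `te_library`
#' @export
te_library <- function(seqs, family, subgroup = NULL) {
  stopifnot(is.character(seqs), !is.null(names(seqs)),
            length(family) == length(seqs))
  structure(list(seqs = seqs, family = family,
                 subgroup = subgroup %||% rep(NA_character_, length(seqs))),
            class = "te_library")
}

#' Classify one protein against a TE library
#'
#' Best local hit determines the family when it reaches both the identity
#' and the query-coverage threshold; otherwise "unclassified". Coverage is
#' measured on the classified protein (the query) so that partial
#' pseudogene ORFs remain classifiable.
#'
#' @param protein amino-acid sequence (single string)
#' @param library a [te_library()]
#' @param min_identity minimum local identity fraction (default 0.30)
#' @param min_coverage minimum query coverage (default 0.50)
#' @return family label or "unclassified"
#' @export
classify_te <- function(protein, library, min_identity = 0.30,
                        min_coverage = 0.50) {
  stopifnot(inherits(library, "te_library"), length(library$seqs) > 0)
  scheme <- scoring_scheme("protein")
  scores <- sw_score_batch(unname(library$seqs), protein, scheme)
  for (k in order(-scores, names(library$seqs))) {
    if (scores[k] <= 0) break
    al <- local_align(protein, library$seqs[[k]], scheme)
    if (al$identity_fraction >= min_identity && al$query_coverage >= min_coverage) {
      return(library$family[k])
    }
  }
  "unclassified"
}

# longest ORF (aa) across 6 frames of a nucleotide span; pseudogene stand-in
longest_orf_protein <- function(nt) {
  if (nchar(nt) < 3) return("")
  frames <- six_frame_translate(Biostrings::DNAStringSet(nt))
  best <- ""
  for (aa in frames$aa) {
    for (piece in strsplit(aa, "*", fixed = TRUE)[[1]]) {
      if (nchar(piece) > nchar(best)) best <- piece
    }
  }
  best
}

#' TE census of a genome
#'
#' Classifies every protein-coding gene and every pseudogene (via its
#' longest ORF translation) against the library and tabulates per-family
#' gene/pseudogene/total counts, the genome totals, and the TE density
#' (TE-associated protein-coding genes per Mb).
#'
#' @param genome an `annotated_genome`
#' @param library a [te_library()]
#' @param min_identity,min_coverage thresholds for [classify_te()]
#' @return a `te_census`: list with `by_family` (family, genes,
#'   pseudogenes, total), `assignments` (locus_tag, replicon, kind,
#'   family), `total_genes`, `total_pseudogenes`, `density_per_mb`
#' @export
te_census <- function(genome, library, min_identity = 0.30,
                      min_coverage = 0.50) {
  ft <- feature_table(genome)
  cand <- ft[ft$kind %in% c("CDS", "pseudogene"), , drop = FALSE]
  fams <- character(nrow(cand))
  if (nrow(cand)) {
    prot <- proteome_seqs(genome)
    for (k in seq_len(nrow(cand))) {
      if (cand$kind[k] == "CDS") {
        aa <- prot[[cand$locus_tag[k]]] %||% ""
      } else {
        r <- genome$replicons[[cand$replicon[k]]]
        nt <- substr(r$sequence, cand$start[k] + 1L, cand$end[k])
        aa <- longest_orf_protein(nt)
      }
      fams[k] <- if (nchar(aa) >= 10)
        classify_te(aa, library, min_identity, min_coverage) else "unclassified"
    }
  }
  assignments <- data.frame(locus_tag = cand$locus_tag, replicon = cand$replicon,
                            kind = cand$kind, family = fams,
                            stringsAsFactors = FALSE)
  te <- assignments[assignments$family != "unclassified", , drop = FALSE]
  fam_levels <- sort(unique(te$family))
  by_family <- do.call(rbind, lapply(fam_levels, function(f) {
    x <- te[te$family == f, ]
    data.frame(family = f,
               genes = sum(x$kind == "CDS"),
               pseudogenes = sum(x$kind == "pseudogene"),
               total = nrow(x), stringsAsFactors = FALSE)
  })) %||% data.frame(family = character(), genes = integer(),
                      pseudogenes = integer(), total = integer(),
                      stringsAsFactors = FALSE)
  mb <- genome_length(genome) / 1e6
  structure(list(by_family = by_family, assignments = assignments,
                 total_genes = sum(te$kind == "CDS"),
                 total_pseudogenes = sum(te$kind == "pseudogene"),
                 density_per_mb = sum(te$kind == "CDS") / mb),
            class = "te_census")
}

#' @export
print.te_census <- function(x, ...) {
  cat(sprintf("<te_census> %d TE genes + %d TE pseudogenes, %.1f TE genes/Mb\n",
              x$total_genes, x$total_pseudogenes, x$density_per_mb))
  if (nrow(x$by_family)) print(x$by_family)
  invisible(x)
}

#' RGP calling configuration
#'
#' Composite genomic-island style thresholds; all defaults are
#' config-exposed package choices on typical genomic-island literature
#' scales.
#'
#' @param window,step sliding window size and step in bp
#' @param gc_z GC deviation flag threshold: `|z| >=` this value
#' @param poverty_frac ortholog-poverty flag: at least this fraction of
#'   window genes without orthologs in the designated close relatives
#' @param te_min TE-cluster flag: at least this many TE genes per window
#' @param min_indicators flags needed per window (2 of 3)
#' @param merge_gap merge flagged regions closer than this (bp)
#' @param min_length drop merged regions shorter than this (bp)
#' @return an `rgp_config`
#' @export
rgp_config <- function(window = 5000L, step = 1000L, gc_z = 1.5,
                       poverty_frac = 0.60, te_min = 3L,
                       min_indicators = 2L, merge_gap = 5000L,
                       min_length = 10000L) {
  stopifnot(window >= step, step > 0, gc_z > 0, poverty_frac > 0, te_min > 0,
            min_indicators >= 1, merge_gap >= 0, min_length >= 0)
  structure(list(window = as.integer(window), step = as.integer(step),
                 gc_z = gc_z, poverty_frac = poverty_frac,
                 te_min = as.integer(te_min),
                 min_indicators = as.integer(min_indicators),
                 merge_gap = as.integer(merge_gap),
                 min_length = as.integer(min_length)),
            class = "rgp_config")
}

#' Windowed GC deviation profile of a replicon
#'
#' Per-window GC fraction standardized against the whole-replicon GC, with
#' the binomial sampling deviation `sqrt(mu * (1 - mu) / window)` as the
#' scale. A model-based scale is used rather than the empirical standard
#' deviation of the window GC values: islands of deviant composition
#' broaden that empirical distribution and would mask themselves. A
#' constant-composition replicon yields all-zero z-scores.
#'
#' @param repl a `replicon` (or nucleotide string)
#' @param config an [rgp_config()]
#' @return data.frame (start, end, gc, z); 0-based half-open windows
#' @export
gc_deviation_profile <- function(repl, config = rgp_config()) {
  seqstr <- if (inherits(repl, "replicon")) repl$sequence else repl
  len <- nchar(seqstr)
  w <- config$window
  if (len < w) stopf("replicon shorter than one window")
  starts <- seq(0L, len - w, by = config$step)
  x <- Biostrings::DNAString(seqstr)
  v <- Biostrings::Views(x, start = starts + 1L, width = w)
  fr <- Biostrings::letterFrequency(v, c("A", "C", "G", "T"))
  gc <- (fr[, "G"] + fr[, "C"]) / pmax(rowSums(fr), 1)
  mu <- gc_content(seqstr) / 100
  sdev <- sqrt(mu * (1 - mu) / w)
  z <- if (is.na(sdev) || sdev == 0) rep(0, length(gc)) else (gc - mu) / sdev
  data.frame(start = starts, end = starts + w, gc = gc, z = z)
}

# merge flagged window intervals; returns data.frame(start, end) sorted
.merge_intervals <- function(starts, ends, gap) {
  if (length(starts) == 0) return(data.frame(start = integer(), end = integer()))
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  ms <- starts[1]; me <- ends[1]
  out <- list()
  for (k in seq_along(starts)[-1]) {
    if (starts[k] <= me + gap) {
      me <- max(me, ends[k])
    } else {
      out[[length(out) + 1]] <- c(ms, me)
      ms <- starts[k]; me <- ends[k]
    }
  }
  out[[length(out) + 1]] <- c(ms, me)
  data.frame(start = vapply(out, `[`, numeric(1), 1),
             end = vapply(out, `[`, numeric(1), 2))
}

#' Call regions of enhanced genome plasticity
#'
#' Windows of each chromosome are scored on three indicators: GC deviation
#' (`|z| >= gc_z`), ortholog poverty (fraction of window genes without an
#' ortholog in any designated close relative), and TE clustering (TE genes
#' per window). Windows reaching `min_indicators` are merged (gap <=
#' `merge_gap`), short regions dropped, and ids assigned in coordinate
#' order per replicon. Plasmid replicons are emitted whole as RGPs
#' regardless of signals.
#'
#' @param genome an `annotated_genome`
#' @param ortholog_tables list of [bbh_orthologs()] tables against close
#'   relatives (queries = this genome's locus tags); may be empty
#' @param census a [te_census()] of this genome (or NULL for no TE signal)
#' @param config an [rgp_config()]
#' @return data.frame (id, replicon, start, end, gc, ortholog_poverty,
#'   te_cluster, whole_plasmid) with 0-based half-open intervals
#' @export
call_rgp <- function(genome, ortholog_tables = list(), census = NULL,
                     config = rgp_config()) {
  with_ortho <- unique(unlist(lapply(ortholog_tables, function(t) t$query)))
  te_tags <- character(0)
  if (!is.null(census)) {
    te_tags <- census$assignments$locus_tag[census$assignments$family != "unclassified"]
  }
  ft <- feature_table(genome)
  out <- list()
  for (r in genome$replicons) {
    prefix <- genome$genome_id
    if (r$role == "plasmid") {
      out[[length(out) + 1]] <- data.frame(
        id = NA_character_, replicon = r$name, start = 0L,
        end = nchar(r$sequence), gc = FALSE, ortholog_poverty = FALSE,
        te_cluster = FALSE, whole_plasmid = TRUE, stringsAsFactors = FALSE)
      next
    }
    if (nchar(r$sequence) < config$window) next
    prof <- gc_deviation_profile(r, config)
    genes <- ft[ft$replicon == r$name & ft$kind == "CDS", , drop = FALSE]
    mid <- (genes$start + genes$end) / 2
    flags <- matrix(FALSE, nrow(prof), 3,
                    dimnames = list(NULL, c("gc", "ortholog_poverty", "te_cluster")))
    flags[, "gc"] <- abs(prof$z) >= config$gc_z
    for (k in seq_len(nrow(prof))) {
      in_w <- mid >= prof$start[k] & mid < prof$end[k]
      n_genes <- sum(in_w)
      if (n_genes > 0) {
        poor <- sum(!(genes$locus_tag[in_w] %in% with_ortho))
        flags[k, "ortholog_poverty"] <- (poor / n_genes) >= config$poverty_frac
      }
      flags[k, "te_cluster"] <- sum(genes$locus_tag[in_w] %in% te_tags) >= config$te_min
    }
    hit <- rowSums(flags) >= config$min_indicators
    if (!any(hit)) next
    merged <- .merge_intervals(prof$start[hit], prof$end[hit], config$merge_gap)
    merged <- merged[merged$end - merged$start >= config$min_length, , drop = FALSE]
    if (nrow(merged) == 0) next
    ev <- t(vapply(seq_len(nrow(merged)), function(k) {
      inside <- hit & prof$start >= merged$start[k] & prof$end <= merged$end[k]
      apply(flags[inside, , drop = FALSE], 2, any)
    }, logical(3)))
    out[[length(out) + 1]] <- data.frame(
      id = NA_character_, replicon = r$name,
      start = as.integer(merged$start), end = as.integer(merged$end),
      gc = ev[, 1], ortholog_poverty = ev[, 2], te_cluster = ev[, 3],
      whole_plasmid = FALSE, stringsAsFactors = FALSE)
  }
  rgp <- do.call(rbind, out) %||% data.frame(
    id = character(), replicon = character(), start = integer(),
    end = integer(), gc = logical(), ortholog_poverty = logical(),
    te_cluster = logical(), whole_plasmid = logical(), stringsAsFactors = FALSE)
  if (nrow(rgp)) {
    rgp <- rgp[order(match(rgp$replicon, names(genome$replicons)), rgp$start), ]
    rgp$id <- sprintf("%s-RGP %d", genome$genome_id, seq_len(nrow(rgp)))
    rownames(rgp) <- NULL
  }
  rgp
}

#' Export RGP intervals as BED
#' @param rgp data.frame from [call_rgp()]
#' @param path output path
#' @return invisibly, `path`
#' @export
write_rgp_bed <- function(rgp, path) {
  bed <- data.frame(chrom = rgp$replicon, chromStart = rgp$start,
                    chromEnd = rgp$end, name = gsub(" ", "_", rgp$id))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
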