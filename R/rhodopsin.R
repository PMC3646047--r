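# Two-stage metagenome rhodopsin screen. Stage 1: every read is translated
# in six frames and locally aligned against a labelled rhodopsin query
# panel at a non-stringent significance cutoff of 1. Stage 2 re-validates
# candidates at a read-length-adaptive cutoff (1e-20 when the sample's
# mean read length exceeds 150 bp, 1e-10 otherwise) plus a coverage rule
# (>= 60% of the reference OR >= 80% of the query must be aligned), then
# each read is classified by its best reference's main group and, for
# xanthorhodopsins, subgroup. Abundances are normalized per-mille of the
# sample's total reads.

RHODOPSIN_GROUPS <- c("proteorhodopsin", "xanthorhodopsin", "fungal",
                      "bacteriorhodopsin", "halorhodopsin", "sensory")

#' Labelled rhodopsin reference set
#'
#' @param seqs named character vector of opsin protein sequences
#' @param group main-group label per record (see `RHODOPSIN_GROUPS`)
#' @param subgroup xanthorhodopsin subgroup ("I"/"II") per record, NA
#'   elsewhere
#' @param require_full if TRUE (query-panel use) every main group must
#'   have at least two representatives
#' @return a `rhodopsin_refs`
#' @export
rhodopsin_refs <- function(seqs, group, subgroup = NULL, require_full = TRUE) {
  stopifnot(is.character(seqs), !is.null(names(seqs)),
            length(group) == length(seqs), !anyDuplicated(names(seqs)))
  bad <- setdiff(unique(group), RHODOPSIN_GROUPS)
  if (length(bad)) stopf("unknown rhodopsin group(s): %s", paste(bad, collapse = ","))
  if (require_full) {
    tab <- table(factor(group, levels = RHODOPSIN_GROUPS))
    if (any(tab < 2)) {
      stopf("query set needs >= 2 representatives per main group; missing: %s",
            paste(names(tab)[tab < 2], collapse = ","))
    }
  }
  structure(list(seqs = seqs, group = group,
                 subgroup = subgroup %||% rep(NA_character_, length(seqs))),
            class = "rhodopsin_refs")
}

#' Read a rhodopsin reference FASTA with labelled headers
#'
#' Headers follow `>id|group|subgroup` (subgroup empty for non-xantho
#' records).
#'
#' @param path FASTA file
#' @param require_full see [rhodopsin_refs()]
#' @return a `rhodopsin_refs`
#' @export
read_rhodopsin_refs <- function(path, require_full = TRUE) {
  x <- read_fasta_protein(path)
  parts <- strsplit(names(x), "|", fixed = TRUE)
  ids <- vapply(parts, `[`, character(1), 1)
  grp <- vapply(parts, `[`, character(1), 2)
  sg <- vapply(parts, function(p) if (length(p) >= 3 && nzchar(p[3])) p[3]
               else NA_character_, character(1))
  rhodopsin_refs(stats::setNames(unname(x), ids), grp, sg, require_full)
}

#' Write a rhodopsin reference set as labelled FASTA
#' @param refs a `rhodopsin_refs`
#' @param path output path
#' @return invisibly, `path`
#' @export
write_rhodopsin_refs <- function(refs, path) {
  hdr <- sprintf("%s|%s|%s", names(refs$seqs), refs$group,
                 ifelse(is.na(refs$subgroup), "", refs$subgroup))
  write_fasta(stats::setNames(refs$seqs, hdr), path, "protein")
}

#' A metagenome sample
#'
#' @param reads named character vector (or `DNAStringSet`) of reads
#' @param total_reads total read count of the survey (>= reads supplied;
#'   defaults to the number of reads)
#' @param mean_read_length mean read length in bp (computed when NULL)
#' @param habitat free-text habitat tag
#' @return a `metagenome_sample`
#' @export
metagenome_sample <- function(reads, total_reads = NULL,
                              mean_read_length = NULL, habitat = "unknown") {
  if (is(reads, "DNAStringSet")) reads <- stats::setNames(as.character(reads), names(reads))
  if (is.null(names(reads))) names(reads) <- sprintf("read%07d", seq_along(reads))
  total_reads <- total_reads %||% length(reads)
  stopifnot(total_reads >= length(reads))
  mean_read_length <- mean_read_length %||% mean(nchar(reads))
  stopifnot(mean_read_length > 0)
  structure(list(reads = reads, total_reads = as.double(total_reads),
                 mean_read_length = mean_read_length, habitat = habitat),
            class = "metagenome_sample")
}

#' Screen configuration
#'
#' @param stage1_evalue non-stringent primary cutoff (1.0)
#' @param stage2_evalue_short stringent cutoff for short-read samples
#'   (mean length <= `read_length_threshold`): 1e-10
#' @param stage2_evalue_long stringent cutoff for long-read samples: 1e-20
#' @param read_length_threshold boundary in bp (150; strictly greater
#'   selects the long-read cutoff)
#' @param min_ref_coverage,min_query_coverage coverage disjunction: an
#'   alignment must cover >= 60% of the reference OR >= 80% of the query
#' @param min_reads minimum survey size; samples must have more than this
#'   many reads (100,000)
#' @return a `screen_config`
#' @export
screen_config <- function(stage1_evalue = 1.0,
                          stage2_evalue_short = 1e-10,
                          stage2_evalue_long = 1e-20,
                          read_length_threshold = 150,
                          min_ref_coverage = 0.60,
                          min_query_coverage = 0.80,
                          min_reads = 100000) {
  stopifnot(stage2_evalue_short < stage1_evalue,
            stage2_evalue_long < stage1_evalue)
  structure(list(stage1_evalue = stage1_evalue,
                 stage2_evalue_short = stage2_evalue_short,
                 stage2_evalue_long = stage2_evalue_long,
                 read_length_threshold = read_length_threshold,
                 min_ref_coverage = min_ref_coverage,
                 min_query_coverage = min_query_coverage,
                 min_reads = min_reads),
            class = "screen_config")
}

#' Stage-2 e-value cutoff selected by mean read length
#'
#' Step function: strictly more than 150 bp mean read length selects the
#' stringent 1e-20 cutoff; 150 bp or less selects 1e-10.
#'
#' @param mean_read_length sample mean read length (bp)
#' @param config a [screen_config()]
#' @return numeric cutoff
#' @export
stage2_cutoff <- function(mean_read_length, config = screen_config()) {
  if (mean_read_length > config$read_length_threshold)
    config$stage2_evalue_long else config$stage2_evalue_short
}

#' Coverage acceptance rule
#'
#' @param ref_coverage aligned fraction of the reference protein
#' @param query_coverage aligned fraction of the translated query frame
#' @param config a [screen_config()]
#' @return logical
#' @export
passes_coverage <- function(ref_coverage, query_coverage,
                            config = screen_config()) {
  ref_coverage >= config$min_ref_coverage |
    query_coverage >= config$min_query_coverage
}

# shared machinery: best SW score of every read frame against the pooled
# reference panel (separated so no alignment can cross records)
.screen_scores <- function(sample, refs, scheme) {
  frames <- six_frame_translate(sample$reads)
  frames <- frames[nchar(frames$aa) > 0, ]
  db <- paste(refs$seqs, collapse = cc(rep("*", 10)))
  frames$score <- sw_score_batch(frames$aa, db, scheme)
  db_len <- sum(nchar(refs$seqs))
  frames$evalue <- evalue_surrogate(frames$score, nchar(frames$aa), db_len, scheme)
  frames
}

#' Primary metagenome screen (stage 1)
#'
#' Translated six-frame local search of every read against the pooled
#' query panel; reads with any hit at significance <= the non-stringent
#' cutoff are retained as candidates.
#'
#' @param sample a [metagenome_sample()]; must exceed the 100,000-read
#'   survey-size minimum or the screen refuses to run
#' @param refs a [rhodopsin_refs()] query panel
#' @param config a [screen_config()]
#' @return data.frame (read_id, frame, score, evalue) of candidate reads
#'   (best frame per read)
#' @export
stage1_screen <- function(sample, refs, config = screen_config()) {
  stopifnot(inherits(sample, "metagenome_sample"),
            inherits(refs, "rhodopsin_refs"))
  if (sample$total_reads <= config$min_reads) {
    stopf(paste0("sample refused: %.0f reads; only surveys with more than ",
                 "%.0f reads are evaluated (small-survey bias rule)"),
          sample$total_reads, config$min_reads)
  }
  scheme <- scoring_scheme("protein")
  frames <- .screen_scores(sample, refs, scheme)
  dt <- data.table::as.data.table(frames)
  best <- dt[order(evalue, frame), .SD[1], by = read]
  cand <- best[best$evalue <= config$stage1_evalue, ]
  out <- data.frame(read_id = names(sample$reads)[cand$read],
                    read = cand$read, frame = cand$frame,
                    score = cand$score, evalue = cand$evalue,
                    stringsAsFactors = FALSE)
  out[order(out$read), ]
}

#' Validate and attribute candidates (stage 2)
#'
#' The stringent cutoff is chosen from the sample's mean read length, each
#' surviving candidate's best frame is re-aligned against every reference,
#' the best reference (ties: identity, then reference id) is retained, and
#' the hit is kept iff its significance passes the cutoff and the
#' alignment covers >= 60% of the reference or >= 80% of the query frame.
#'
#' @param candidates stage-1 output
#' @param refs a [rhodopsin_refs()]
#' @param sample the same [metagenome_sample()]
#' @param config a [screen_config()]
#' @return data.frame (read_id, ref_id, group, subgroup, score, evalue,
#'   identity, ref_coverage, query_coverage)
#' @export
stage2_validate <- function(candidates, refs, sample,
                            config = screen_config()) {
  cutoff <- stage2_cutoff(sample$mean_read_length, config)
  empty <- data.frame(read_id = character(), ref_id = character(),
                      group = character(), subgroup = character(),
                      score = integer(), evalue = numeric(),
                      identity = numeric(), ref_coverage = numeric(),
                      query_coverage = numeric(), stringsAsFactors = FALSE)
  surv <- candidates[candidates$evalue <= cutoff, , drop = FALSE]
  if (nrow(surv) == 0) return(empty)
  scheme <- scoring_scheme("protein")
  db_len <- sum(nchar(refs$seqs))
  frames <- six_frame_translate(sample$reads[surv$read])
  rows <- list()
  for (k in seq_len(nrow(surv))) {
    aa <- frames$aa[frames$read == k & frames$frame == surv$frame[k]]
    if (length(aa) != 1 || nchar(aa) == 0) next
    als <- lapply(refs$seqs, function(r)
      local_align(aa, r, scheme, search_space = db_len))
    sc <- vapply(als, `[[`, numeric(1), "score")
    id <- vapply(als, `[[`, numeric(1), "identity_fraction")
    ord <- order(-sc, -id, names(refs$seqs))
    bestk <- ord[1]
    al <- als[[bestk]]
    if (al$evalue > cutoff) next
    if (!passes_coverage(al$subject_coverage, al$query_coverage, config)) next
    rows[[length(rows) + 1]] <- data.frame(
      read_id = surv$read_id[k], ref_id = names(refs$seqs)[bestk],
      group = refs$group[bestk], subgroup = refs$subgroup[bestk],
      score = al$score, evalue = al$evalue,
      identity = al$identity_fraction,
      ref_coverage = al$subject_coverage,
      query_coverage = al$query_coverage, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows) %||% empty
  rownames(out) <- NULL
  out
}

#' Abundance profile from validated hits
#'
#' Counts per main group (and xanthorhodopsin subgroup), normalized
#' against the sample's total reads and reported per-mille, plus the
#' subgroup-II percentage of all validated rhodopsin reads.
#'
#' @param validated stage-2 output
#' @param sample the [metagenome_sample()]
#' @return an `abundance_profile`: list with `by_group` (group, subgroup,
#'   count, per_mille), `total_count`, `total_per_mille`,
#'   `subgroup2_percent`
#' @export
classify_hits <- function(validated, sample) {
  total <- sample$total_reads
  keys <- data.frame(
    group = c(RHODOPSIN_GROUPS[RHODOPSIN_GROUPS != "xanthorhodopsin"],
              "xanthorhodopsin", "xanthorhodopsin"),
    subgroup = c(rep(NA_character_, 5), "I", "II"), stringsAsFactors = FALSE)
  cnt <- integer(nrow(keys))
  for (k in seq_len(nrow(keys))) {
    if (is.na(keys$subgroup[k])) {
      cnt[k] <- sum(validated$group == keys$group[k])
    } else {
      cnt[k] <- sum(validated$group == keys$group[k] &
                      !is.na(validated$subgroup) &
                      validated$subgroup == keys$subgroup[k])
    }
  }
  by_group <- cbind(keys, count = cnt, per_mille = 1000 * cnt / total)
  n_total <- nrow(validated)
  sg2 <- if (n_total > 0) 100 * by_group$count[by_group$group == "xanthorhodopsin" &
                                                 by_group$subgroup == "II"] / n_total else 0
  structure(list(by_group = by_group,
                 total_count = n_total,
                 total_per_mille = 1000 * n_total / total,
                 subgroup2_percent = sg2),
            class = "abundance_profile")
}

#' @export
print.abundance_profile <- function(x, ...) {
  cat(sprintf("<abundance_profile> %d validated rhodopsin reads (%.3f per mille); subgroup II %.1f%%\n",
              x$total_count, x$total_per_mille, x$subgroup2_percent))
  print(x$by_group)
  invisible(x)
}

#' Run the full two-stage screen on one sample
#'
#' @inheritParams stage1_screen
#' @return list(candidates, validated, profile)
#' @export
run_screen <- function(sample, refs, config = screen_config()) {
  cand <- stage1_screen(sample, refs, config)
  val <- stage2_validate(cand, refs, sample, config)
  list(candidates = cand, validated = val,
       profile = classify_hits(val, sample))
}

# ---- binding-site profiling --------------------------------------------

#' Keto-carotenoid binding-site specification
#'
#' Positions are 1-based residue numbers on the reference xanthorhodopsin.
#' The seven positions named in the comparative analysis (156, 160, 194,
#' 197, 198, 201, 205) are the default; the full binding site comprises 16
#' residues and further positions can be supplied. Position 156 drives the
#' binding verdict: only a small residue (G/A/S) leaves room for the
#' keto-carotenoid ring.
#'
#' @param positions integer vector of reference positions
#' @param key_position the ring-pocket position (156)
#' @return a `binding_site_spec`
#' @export
binding_site_spec <- function(positions = c(156L, 160L, 194L, 197L, 198L, 201L, 205L),
                              key_position = 156L) {
  stopifnot(length(positions) >= 1, length(positions) <= 16,
            key_position %in% positions)
  structure(list(positions = sort(unique(as.integer(positions))),
                 key_position = as.integer(key_position)),
            class = "binding_site_spec")
}

#' Binding-site conservation profile of one opsin
#'
#' The opsin is globally aligned to the reference xanthorhodopsin; at each
#' spec position the aligned residue is compared (identity; similarity =
#' positive substitution score). The verdict is "possible" iff the residue
#' at the 156-equivalent column is small (G, A or S), else "abolished".
#' If any spec position falls on a gapped column the profile is flagged
#' partial (NA verdict components are reported for those positions).
#'
#' @param opsin protein sequence to profile
#' @param spec a [binding_site_spec()]
#' @param reference reference xanthorhodopsin sequence carrying the
#'   numbering
#' @return a `binding_site_profile`: list with per-position table,
#'   identities, similarities, residue at the key position, `partial`
#'   flag, and `verdict`
#' @export
binding_site_profile <- function(opsin, spec = binding_site_spec(), reference) {
  stopifnot(inherits(spec, "binding_site_spec"))
  if (max(spec$positions) > nchar(reference)) {
    stopf("reference (%d aa) shorter than spec position %d",
          nchar(reference), max(spec$positions))
  }
  scheme <- scoring_scheme("protein")
  al <- global_align(reference, opsin, scheme)
  ra <- chars(al$aligned_query)   # reference row
  rb <- chars(al$aligned_subject) # opsin row
  refpos <- cumsum(ra != "-")
  cols <- match(spec$positions, refpos)
  res <- rb[cols]
  refres <- ra[cols]
  aligned <- !is.na(res) & res != "-"
  identical_at <- aligned & res == refres
  similar_at <- aligned & vapply(seq_along(cols), function(k) {
    if (!aligned[k]) return(FALSE)
    scheme$matrix[refres[k], res[k]] > 0
  }, logical(1))
  key_col <- match(spec$key_position, refpos)
  key_res <- rb[key_col]
  partial <- any(!aligned)
  verdict <- if (!is.na(key_res) && key_res %in% c("G", "A", "S"))
    "possible" else "abolished"
  structure(list(
    table = data.frame(position = spec$positions, reference = refres,
                       residue = res, identical = identical_at,
                       similar = similar_at, stringsAsFactors = FALSE),
    identities = sum(identical_at),
    similarities = sum(similar_at),
    n_positions = length(spec$positions),
    key_residue = key_res,
    partial = partial,
    verdict = verdict
  ), class = "binding_site_profile")
}

#' @export
print.binding_site_profile <- function(x, ...) {
  cat(sprintf("<binding_site_profile> %d/%d identities, %d similarities, key residue %s -> binding %s%s\n",
              x$identities, x$n_positions, x$similarities, x$key_residue,
              x$verdict, if (x$partial) " (partial)" else ""))
  invisible(x)
}

#' Assign a xanthorhodopsin subgroup by nearest reference
#'
#' Global identity against every xanthorhodopsin reference; the best
#' subgroup wins if its best identity reaches the 0.30 homology floor and
#' leads the other subgroup by at least 2 identity points, else
#' "unassigned".
#'
#' @param opsin protein sequence
#' @param refs a [rhodopsin_refs()] containing both subgroups
#' @param min_identity homology floor (0.30)
#' @param margin minimum identity lead between subgroups (0.02)
#' @return "I", "II" or "unassigned"
#' @export
assign_subgroup <- function(opsin, refs, min_identity = 0.30, margin = 0.02) {
  xi <- which(refs$group == "xanthorhodopsin")
  sgs <- refs$subgroup[xi]
  stopifnot(all(c("I", "II") %in% sgs))
  scheme <- scoring_scheme("protein")
  ids <- vapply(refs$seqs[xi], function(r)
    global_align(opsin, r, scheme)$identity_fraction, numeric(1))
  best_i <- max(ids[sgs == "I"])
  best_ii <- max(ids[sgs == "II"])
  if (max(best_i, best_ii) < min_identity) return("unassigned")
  if (abs(best_i - best_ii) < margin) return("unassigned")
  if (best_i > best_ii) "I" else "II"
}
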