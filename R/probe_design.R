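# Primary probe panel and readout sequence design.
#
# Primary probes are 35-nt reverse complements of target windows tiled with
# a 2-nt gap, kept when GC lies in [0.40, 0.65], screened for off-target and
# cross-hybridization by exact contiguous 17-mer sharing (either
# orientation), and a gene is retained only if >= 24 probes survive.
# Readouts are random 15-nt sequences with GC in [0.40, 0.60] screened for
# any contiguous 10-nt transcriptome match.

#' Probe design parameter defaults
#'
#' @return list with `probe_len` (35 nt), `spacing` (2 nt), `gc_min` (0.40),
#'   `gc_max` (0.65), `offtarget_k` (17 nt), `crosshyb_k` (17 nt),
#'   `min_probes` (24).
#' @export
probe_params <- function() {
  list(probe_len = 35L, spacing = 2L, gc_min = 0.40, gc_max = 0.65,
       offtarget_k = 17L, crosshyb_k = 17L, min_probes = 24L)
}

#' Readout design parameter defaults
#'
#' @return list with `readout_len` (15 nt), `gc_min` (0.40), `gc_max`
#'   (0.60), `screen_k` (10 nt), `max_draws` (1e6 per accepted sequence).
#' @export
readout_params <- function() {
  list(readout_len = 15L, gc_min = 0.40, gc_max = 0.60, screen_k = 10L,
       max_draws = 1e6)
}

# as.character() drops names (e.g. on DNAStringSet input they survive, on
# named character vectors they do not); keep them either way
as_named_chr <- function(x) {
  s <- as.character(x)
  if (is.null(names(s))) names(s) <- names(x)
  s
}

gc_fraction <- function(seqs) {
  n <- nchar(seqs)
  gc <- vapply(seqs, function(s) {
    v <- strsplit(s, "", fixed = TRUE)[[1]]
    sum(v %in% c("G", "C"))
  }, 0, USE.NAMES = FALSE)
  gc / n
}

revcomp <- function(seqs) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs)))
}

# all k-mers of a set of sequences (character vector)
kmers_of <- function(seqs, k) {
  out <- lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < k) return(character())
    substring(s, 1:(L - k + 1), k:L)
  })
  unlist(out, use.names = FALSE)
}

#' Tile candidate probe windows along a target
#'
#' Windows start at 1, `probe_len + spacing + 1`, ... so successive windows
#' never overlap and are separated by exactly `spacing` nt; the count is
#' `floor((L - probe_len) / (probe_len + spacing)) + 1`.
#'
#' @param target_seq DNA string over A/C/G/T.
#' @param probe_len window length in nt (default 35).
#' @param spacing gap between successive windows in nt (default 2).
#' @return data.frame `start` (1-based), `window` (sequence), `gc`.
#' @export
tile_candidates <- function(target_seq, probe_len = 35L, spacing = 2L) {
  target_seq <- toupper(as.character(target_seq))
  L <- nchar(target_seq)
  if (L < probe_len) {
    warning("target shorter than probe_len; no candidate windows")
    return(data.frame(start = integer(), window = character(), gc = numeric()))
  }
  step <- probe_len + spacing
  starts <- seq.int(1L, L - probe_len + 1L, by = step)
  windows <- substring(target_seq, starts, starts + probe_len - 1L)
  data.frame(start = starts, window = windows, gc = gc_fraction(windows))
}

#' Retain windows by GC content
#'
#' Bounds are inclusive at both ends.
#'
#' @param windows data.frame as from [tile_candidates()].
#' @param gc_min,gc_max GC fraction bounds (defaults 0.40, 0.65).
#' @return the retained rows.
#' @export
gc_filter <- function(windows, gc_min = 0.40, gc_max = 0.65) {
  windows[windows$gc >= gc_min & windows$gc <= gc_max, , drop = FALSE]
}

#' Off-target screen by exact k-mer sharing
#'
#' A window is removed iff it shares a contiguous exact match of >= `k` nt
#' (sense or antisense) with any transcript other than the target: a window
#' k-mer, or its reverse complement, occurring in the off-target k-mer index
#' is equivalent to a shared match of length >= k.
#'
#' @param windows data.frame with a `window` column.
#' @param transcripts named `DNAStringSet` (or named character vector) of
#'   the transcriptome.
#' @param target_id name of the intended target (excluded from the index).
#' @param k minimum off-target match length in nt (default 17).
#' @return the retained rows.
#' @export
offtarget_screen <- function(windows, transcripts, target_id, k = 17L) {
  seqs <- as_named_chr(transcripts)
  if (!target_id %in% names(seqs))
    stop("target_id '", target_id, "' absent from transcripts")
  index <- unique(kmers_of(seqs[setdiff(names(seqs), target_id)], k))
  if (!length(index) || !nrow(windows)) return(windows)
  hit <- vapply(windows$window, function(w) {
    km <- kmers_of(w, k)
    any(km %in% index) || any(revcomp(km) %in% index)
  }, NA, USE.NAMES = FALSE)
  windows[!hit, , drop = FALSE]
}

#' Cross-hybridization screen across a multi-gene panel
#'
#' For any contiguous match of >= `k` nt between probes of different genes
#' (either orientation), the probe belonging to the gene currently holding
#' more probes is removed (ties broken by lexicographic gene name), and the
#' screen is re-evaluated until no conflicts remain.
#'
#' @param panel data.frame with columns `gene`, `window` (target-sense
#'   window sequence), plus any others carried through.
#' @param k minimum cross-hybridizing match length in nt (default 17).
#' @return the reduced panel.
#' @export
crosshyb_screen <- function(panel, k = 17L) {
  if (!nrow(panel)) return(panel)
  repeat {
    n <- nrow(panel)
    km <- lapply(panel$window, function(w) unique(kmers_of(w, k)))
    # canonical form so either orientation collides
    canon <- lapply(km, function(x) pmin(x, revcomp(x)))
    all_k <- unlist(canon, use.names = FALSE)
    owner <- rep(panel$gene, lengths(canon))
    conflict_probe <- NA_integer_
    for (i in seq_len(n)) {
      other <- owner[match(canon[[i]], all_k)] # first owner of each k-mer
      # a k-mer held by >1 gene conflicts regardless of match order
      clash <- vapply(canon[[i]], function(kk) {
        g <- unique(owner[all_k == kk])
        length(setdiff(g, panel$gene[i])) > 0
      }, NA)
      if (any(clash)) {
        kk <- canon[[i]][which(clash)[1]]
        genes_in <- unique(owner[all_k == kk])
        counts <- table(panel$gene)[genes_in]
        loser <- genes_in[order(-as.numeric(counts), genes_in)][1]
        members <- which(panel$gene == loser &
                           vapply(canon, function(cc) kk %in% cc, NA))
        conflict_probe <- members[1]
        break
      }
    }
    if (is.na(conflict_probe)) return(panel)
    panel <- panel[-conflict_probe, , drop = FALSE]
  }
}

#' Design a primary probe panel
#'
#' Per target: tile -> GC filter -> off-target screen; then the joint
#' cross-hybridization screen; genes with fewer than `min_probes` surviving
#' probes are dropped and reported. Probe sequences are the reverse
#' complements of the retained target windows; when `readouts` are supplied
#' each gene's probes carry two copies of its assigned readout-complement
#' overhang on the 3' end.
#'
#' @param transcripts named `DNAStringSet` or named character vector.
#' @param targets character vector of target ids (subset of transcript
#'   names).
#' @param params list as from [probe_params()].
#' @param readouts optional character vector of readout sequences, recycled
#'   over genes in order.
#' @return list with `probes` (data.frame `gene, start, window, probe_seq,
#'   overhang_seq, gc`) and `excluded` (data.frame `gene, n_probes,
#'   reason`).
#' @export
design_panel <- function(transcripts, targets, params = probe_params(),
                         readouts = NULL) {
  seqs <- toupper(as_named_chr(transcripts))
  if (!all(targets %in% names(seqs)))
    stop("targets absent from transcripts: ",
         paste(setdiff(targets, names(seqs)), collapse = ", "))
  per_gene <- lapply(targets, function(g) {
    w <- tile_candidates(seqs[[g]], params$probe_len, params$spacing)
    w <- gc_filter(w, params$gc_min, params$gc_max)
    w <- offtarget_screen(w, seqs, g, params$offtarget_k)
    if (nrow(w)) cbind(gene = g, w) else NULL
  })
  panel <- do.call(rbind, per_gene)
  if (is.null(panel)) stop("empty panel: no probes survive for any target")
  panel <- crosshyb_screen(panel, params$crosshyb_k)
  counts <- table(factor(panel$gene, levels = targets))
  kept <- names(counts)[counts >= params$min_probes]
  dropped <- names(counts)[counts < params$min_probes]
  excluded <- data.frame(gene = dropped,
                         n_probes = as.integer(counts[dropped]),
                         reason = rep("fewer than min_probes surviving probes",
                                      length(dropped)))
  panel <- panel[panel$gene %in% kept, , drop = FALSE]
  if (!nrow(panel)) stop("empty panel: no target retains enough probes")
  overhang <- if (is.null(readouts)) "" else {
    ro <- rep_len(revcomp(readouts), length(kept))
    names(ro) <- kept
    ro[panel$gene]
  }
  panel$probe_seq <- paste0(revcomp(panel$window),
                            overhang, overhang) # two overhang repeats, 3'
  panel$overhang_seq <- as.character(overhang)
  rownames(panel) <- NULL
  list(probes = panel[c("gene", "start", "window", "probe_seq",
                        "overhang_seq", "gc")],
       excluded = excluded)
}

# run fn with a private RNG stream seeded by `seed`
with_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Design fluorescent readout sequences
#'
#' Draws random 15-nt sequences with GC in `[gc_min, gc_max]` and rejects
#' any containing a contiguous `screen_k`-nt match (either orientation) to
#' the transcriptome or to a previously accepted readout. Deterministic
#' given `seed`.
#'
#' @param n number of readout sequences required.
#' @param transcripts named `DNAStringSet`/character vector, possibly empty.
#' @param params list as from [readout_params()].
#' @param seed integer RNG seed.
#' @return data.frame `readout_seq, gc`.
#' @export
design_readouts <- function(n, transcripts = character(),
                            params = readout_params(), seed = 1L) {
  stopifnot(n >= 1)
  k <- params$screen_k
  index <- unique(kmers_of(toupper(as_named_chr(transcripts)), k))
  with_seed(seed, function() {
    accepted <- character()
    draws_since_last <- 0
    while (length(accepted) < n) {
      if (draws_since_last >= params$max_draws)
        stop("readout design exhausted after ", params$max_draws,
             " draws; found ", length(accepted), " of ", n)
      draws_since_last <- draws_since_last + 1
      s <- paste(sample(c("A", "C", "G", "T"), params$readout_len,
                        replace = TRUE), collapse = "")
      gc <- gc_fraction(s)
      if (gc < params$gc_min || gc > params$gc_max) next
      km <- kmers_of(s, k)
      if (any(km %in% index) || any(revcomp(km) %in% index)) next
      if (length(accepted) &&
          any(km %in% unlist(lapply(accepted, kmers_of, k))) ||
          length(accepted) &&
          any(revcomp(km) %in% unlist(lapply(accepted, kmers_of, k)))) next
      accepted <- c(accepted, s)
      draws_since_last <- 0
    }
    data.frame(readout_seq = accepted, gc = gc_fraction(accepted))
  })
}

#' Write a probe panel to CSV
#'
#' @param panel result of [design_panel()].
#' @param path output CSV for the probe table; exclusions go to
#'   `<path>.excluded.csv` when any gene was dropped.
#' @export
write_probe_panel <- function(panel, path) {
  utils::write.csv(panel$probes, path, row.names = FALSE, quote = FALSE)
  if (nrow(panel$excluded))
    utils::write.csv(panel$excluded, paste0(path, ".excluded.csv"),
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
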