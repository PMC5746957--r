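## CL-motif score track construction. Crosslink-associated (CL) motifs are
## polypyrimidine-rich sequence patterns enriched at crosslink sites across
## proteins -- a crosslinking bias, not a binding signal. The workflow: call
## sites on the input-control data, export 10-nt windows for external motif
## discovery (DREME), read the discovered motifs back (MEME format), scan the
## genome with an internal FIMO-compatible log-odds scanner (or ingest FIMO's
## own TSV), and reduce overlapping hits to a per-position best-motif score.

DNA_BASES <- c("A", "C", "G", "T")

#' Read motifs from a MEME-format file
#'
#' Parses the minimal MEME motif format (as emitted by DREME and MEME):
#' `MOTIF` lines followed by `letter-probability matrix` blocks, with
#' optional `Background letter frequencies`.
#'
#' @param path MEME-format motif file.
#' @param pseudocount added to matrix entries (then renormalised) so that
#'   zero probabilities do not produce infinite log-odds.
#' @return list of motif models: `id`, `pwm` (4 x length matrix, rows
#'   A, C, G, T), `bg` (length-4 background frequencies).
#' @export
read_meme_motifs <- function(path, pseudocount = 1e-4) {
  lines <- readLines(path)
  bg <- rep(0.25, 4)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at) == 1L && bg_at < length(lines)) {
    tok <- strsplit(trimws(lines[bg_at + 1L]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(tok))
    base_at <- match(DNA_BASES, toupper(tok))
    if (!anyNA(base_at)) bg <- vals[base_at + 1L]
  }
  motifs <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (grepl("^MOTIF", lines[i])) {
      id <- strsplit(trimws(lines[i]), "\\s+")[[1]][2]
      j <- i + 1L
      while (j <= length(lines) &&
             !grepl("^letter-probability matrix", lines[j])) j <- j + 1L
      if (j > length(lines)) break
      rows <- list()
      j <- j + 1L
      while (j <= length(lines)) {
        tok <- suppressWarnings(
          as.numeric(strsplit(trimws(lines[j]), "\\s+")[[1]]))
        if (length(tok) != 4L || anyNA(tok)) break
        rows[[length(rows) + 1L]] <- tok
        j <- j + 1L
      }
      pwm <- t(do.call(rbind, rows))           # 4 x len, rows A C G T
      pwm <- pwm + pseudocount
      pwm <- sweep(pwm, 2, colSums(pwm), "/")
      rownames(pwm) <- DNA_BASES
      motifs[[length(motifs) + 1L]] <- list(id = id, pwm = pwm, bg = bg)
      i <- j
    } else i <- i + 1L
  }
  motifs
}

#' Extract discovery windows around called input crosslink sites
#'
#' For each site, a 10-nt positive window centred on the site and two 10-nt
#' control windows whose centres lie 20 nt upstream and downstream are
#' extracted (the motif-discovery contrast). Minus-strand sites yield
#' reverse-complemented (sense) sequences. Windows clipped at chromosome
#' ends are dropped and counted.
#'
#' @param sites data.frame with `chrom`, `pos` (0-based), `strand`.
#' @param genome named `DNAStringSet` (or FASTA path).
#' @param width window width (default 10; the window is `centre +/- width/2`).
#' @param offset control-centre distance (default 20).
#' @return list with `positive` and `control` `DNAStringSet`s and `dropped`
#'   counts.
#' @export
make_dreme_windows <- function(sites, genome, width = 10L, offset = 20L) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  half <- width %/% 2L
  pos_seq <- list(); ctl_seq <- list()
  dropped <- 0L
  grab <- function(chrom, centre, strand) {
    # 0-based [centre - half, centre + half)
    s <- centre - half
    e <- centre + half
    L <- length(genome[[chrom]])
    if (s < 0L || e > L) return(NULL)
    sq <- Biostrings::subseq(genome[[chrom]], s + 1L, e)
    if (strand == "-") sq <- Biostrings::reverseComplement(sq)
    as.character(sq)
  }
  for (r in seq_len(nrow(sites))) {
    chrom <- sites$chrom[r]
    if (!chrom %in% names(genome)) { dropped <- dropped + 1L; next }
    p <- grab(chrom, sites$pos[r], sites$strand[r])
    if (is.null(p)) { dropped <- dropped + 1L; next }
    pos_seq[[length(pos_seq) + 1L]] <- p
    for (d in c(-offset, offset)) {
      ctl <- grab(chrom, sites$pos[r] + d, sites$strand[r])
      if (is.null(ctl)) { dropped <- dropped + 1L; next }
      ctl_seq[[length(ctl_seq) + 1L]] <- ctl
    }
  }
  list(positive = Biostrings::DNAStringSet(unlist(pos_seq, use.names = FALSE)),
       control = Biostrings::DNAStringSet(unlist(ctl_seq, use.names = FALSE)),
       dropped = dropped)
}

## Exact null distribution of the log-odds score under the background model:
## columns are independent, so the distribution is the convolution of the
## per-column (score, probability) pairs. Scores are rounded to keep the
## support compact.
pwm_score_null <- function(score_mat, bg, digits = 6) {
  dist <- c(`0` = 1)
  for (j in seq_len(ncol(score_mat))) {
    s_old <- as.numeric(names(dist))
    newscore <- as.vector(outer(score_mat[, j], s_old, `+`))
    newprob <- as.vector(outer(bg, dist, `*`))
    key <- sprintf(paste0("%.", digits, "f"), newscore)
    dist <- tapply(newprob, key, sum)
  }
  data.frame(score = as.numeric(names(dist)), prob = as.numeric(dist))
}

#' Scan sequences with position weight matrices (FIMO-compatible)
#'
#' Log-odds scoring (`log2(pwm/bg)` summed over the window) on the sense
#' strand only, keeping windows whose score's p-value under the exact
#' background null of the PWM is at most `thresh` and whose score is
#' positive. Ambiguous bases contribute their background-expected column
#' score.
#'
#' @param motifs list of motif models (see [read_meme_motifs()]).
#' @param genome named `DNAStringSet` or FASTA path.
#' @param thresh p-value threshold (default 0.01, the FIMO default used for
#'   CL-motif tracks).
#' @return data.frame of hits: `chrom`, `start`, `end` (0-based half-open),
#'   `strand` (always `"+"`), `motif` (index), `motif_id`, `score`,
#'   `pvalue`.
#' @export
scan_motifs <- function(motifs, genome, thresh = 0.01) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  hits <- list()
  for (mi in seq_along(motifs)) {
    m <- motifs[[mi]]
    S <- log2(m$pwm / m$bg)                     # 4 x len
    len <- ncol(S)
    null <- pwm_score_null(S, m$bg)
    # P(score >= s) via reverse cumulative sum over the sorted support
    o <- order(null$score)
    cum <- rev(cumsum(rev(null$prob[o])))
    sc_sorted <- null$score[o]
    pval_of <- function(s) {
      i <- findInterval(s - 1e-9, sc_sorted) + 1L
      ifelse(i > length(cum), 0, cum[pmin(i, length(cum))])
    }
    # background-average score for ambiguous bases, per column
    amb <- colSums(S * m$bg)
    Sx <- rbind(S, amb)
    for (chrom in names(genome)) {
      seqch <- strsplit(as.character(genome[[chrom]]), "")[[1]]
      L <- length(seqch)
      if (L < len) next
      idx <- match(seqch, DNA_BASES)
      idx[is.na(idx)] <- 5L
      nw <- L - len + 1L
      sc <- numeric(nw)
      for (j in seq_len(len))
        sc <- sc + Sx[cbind(idx[j:(j + nw - 1L)], j)]
      pv <- pval_of(sc)
      keep <- which(pv <= thresh & sc > 0)
      if (length(keep) == 0L) next
      hits[[length(hits) + 1L]] <- data.frame(
        chrom = chrom, start = keep - 1L, end = keep - 1L + len,
        strand = "+", motif = mi, motif_id = m$id,
        score = sc[keep], pvalue = pv[keep])
    }
  }
  if (length(hits) == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      motif = integer(0), motif_id = character(0),
                      score = numeric(0), pvalue = numeric(0)))
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}

#' Read motif occurrences from a FIMO TSV file
#'
#' Accepts both the modern header (`motif_id ... sequence_name start stop
#' strand score p-value ...`) and the legacy `#pattern name` dialect.
#' Coordinates are converted from FIMO's 1-based inclusive convention to
#' 0-based half-open.
#'
#' @param path FIMO TSV.
#' @return data.frame in the same layout as [scan_motifs()] output (motif
#'   indices assigned in order of first appearance).
#' @export
read_fimo_tsv <- function(path) {
  tab <- utils::read.delim(path, comment.char = "", check.names = FALSE,
                           stringsAsFactors = FALSE)
  nm <- tolower(names(tab))
  pick <- function(...) {
    for (cand in c(...)) {
      i <- which(nm == cand)
      if (length(i)) return(tab[[i[1]]])
    }
    stop("read_fimo_tsv: missing column (tried: ",
         paste(c(...), collapse = ", "), ")")
  }
  motif_id <- as.character(pick("motif_id", "#pattern name", "pattern name"))
  ids <- unique(motif_id)
  data.frame(
    chrom = as.character(pick("sequence_name", "sequence name")),
    start = as.integer(pick("start")) - 1L,
    end = as.integer(pick("stop")),
    strand = as.character(pick("strand")),
    motif = match(motif_id, ids),
    motif_id = motif_id,
    score = as.numeric(pick("score")),
    pvalue = as.numeric(pick("p-value", "pvalue")),
    stringsAsFactors = FALSE)
}

#' Reduce motif hits to a per-position best-motif score track
#'
#' Every position covered by at least one hit carries the index and score of
#' its highest-scoring overlapping motif occurrence (ties broken toward the
#' lower motif index); uncovered positions carry score 0.
#'
#' @param hits data.frame from [scan_motifs()] or [read_fimo_tsv()].
#' @param chrom_sizes named vector of chromosome lengths.
#' @return named list per chromosome, each with integer vector `index`
#'   (0 = no match) and numeric vector `score`.
#' @export
best_score_track <- function(hits, chrom_sizes) {
  track <- lapply(chrom_sizes, function(L)
    list(index = integer(L), score = numeric(L)))
  if (nrow(hits) > 0L) {
    o <- order(hits$motif)     # lower motif index first -> wins score ties
    for (r in o) {
      chrom <- hits$chrom[r]
      if (!chrom %in% names(track)) next
      ix <- (hits$start[r] + 1L):hits$end[r]
      ix <- ix[ix >= 1L & ix <= length(track[[chrom]]$score)]
      better <- ix[hits$score[r] > track[[chrom]]$score[ix]]
      track[[chrom]]$score[better] <- hits$score[r]
      track[[chrom]]$index[better] <- hits$motif[r]
    }
  }
  track
}
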