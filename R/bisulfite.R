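#' Locate CpG dinucleotides in a reference amplicon
#'
#' @param reference DNA string over A/C/G/T (case-insensitive).
#' @return integer vector of 0-based offsets of the C of each CpG,
#'   ascending.
#' @examples
#' find_cpg_sites("ACGTCG")  # 1 4
#' @export
find_cpg_sites <- function(reference) {
  reference <- toupper(reference)
  chars <- strsplit(reference, "", fixed = TRUE)[[1]]
  if (!all(chars %in% c("A", "C", "G", "T")))
    stop("reference contains non-ACGT characters", call. = FALSE)
  n <- length(chars)
  if (n < 2L) return(integer())
  which(chars[-n] == "C" & chars[-1L] == "G") - 1L
}

#' A clone bisulfite-sequencing data set
#'
#' Bundles a reference amplicon (the converted-strand template; only the
#' top strand is modelled) with sequenced clones and the detected CpG
#' sites.
#'
#' @param reference reference amplicon DNA string.
#' @param clones data.frame with columns \code{clone_id},
#'   \code{sample_id}, \code{sequence}.
#' @return object of class \code{clone_set}: list with \code{reference},
#'   \code{clones}, \code{cpg_sites} (0-based).
#' @export
clone_set <- function(reference, clones) {
  stopifnot(all(c("clone_id", "sample_id", "sequence") %in% names(clones)))
  sites <- find_cpg_sites(reference)
  if (!length(sites))
    stop("reference amplicon contains no CpG dinucleotide", call. = FALSE)
  structure(list(reference = toupper(reference),
                 clones = clones, cpg_sites = sites),
            class = "clone_set")
}

# bisulfite-aware substitution score: reference C read as clone T is
# expected after conversion and scores as a match
.bs_score <- function(a, b, match = 1, mismatch = -1) {
  ifelse(a == b | (a == "C" & b == "T"), match, mismatch)
}

#' Bisulfite-aware global pairwise alignment
#'
#' Needleman-Wunsch alignment with affine gaps in which a reference C
#' aligned to a clone T scores as a match (conversion is expected on the
#' sequenced strand); every other mismatch is penalised. Scoring: match
#' +1, mismatch -1, first base of a gap -2, each further base -1. Clones
#' whose alignment identity (match-equivalent columns over all alignment
#' columns) falls below \code{min_identity} are rejected.
#'
#' @param clone clone DNA string (length within ~20\% of the reference).
#' @param reference reference amplicon DNA string.
#' @param match,mismatch,gap_open,gap_extend scoring parameters.
#' @param min_identity rejection threshold (default 0.7).
#' @return list with \code{map} (integer vector over reference positions,
#'   1-based clone position or NA at reference positions aligned to a
#'   gap), \code{score}, \code{identity}, \code{rejected}, \code{reason}.
#' @export
align_clone <- function(clone, reference, match = 1, mismatch = -1,
                        gap_open = -2, gap_extend = -1,
                        min_identity = 0.7) {
  ref <- strsplit(toupper(reference), "", fixed = TRUE)[[1]]
  cln <- strsplit(toupper(clone), "", fixed = TRUE)[[1]]
  n <- length(ref); m <- length(cln)
  if (n == 0L || m == 0L) stop("empty sequence", call. = FALSE)

  NEG <- -1e9
  # state matrices: D diagonal (aligned pair), X gap in clone (reference
  # base unmatched), Y gap in reference (clone insertion)
  D <- matrix(NEG, n + 1L, m + 1L)
  X <- matrix(NEG, n + 1L, m + 1L)
  Y <- matrix(NEG, n + 1L, m + 1L)
  D[1L, 1L] <- 0
  X[-1L, 1L] <- gap_open + gap_extend * (seq_len(n) - 1L)
  Y[1L, -1L] <- gap_open + gap_extend * (seq_len(m) - 1L)
  for (i in seq_len(n) + 1L) {
    s <- .bs_score(ref[i - 1L], cln, match, mismatch)
    for (j in seq_len(m) + 1L) {
      D[i, j] <- max(D[i - 1L, j - 1L], X[i - 1L, j - 1L],
                     Y[i - 1L, j - 1L]) + s[j - 1L]
      X[i, j] <- max(D[i - 1L, j] + gap_open, X[i - 1L, j] + gap_extend,
                     Y[i - 1L, j] + gap_open)
      Y[i, j] <- max(D[i, j - 1L] + gap_open, Y[i, j - 1L] + gap_extend,
                     X[i, j - 1L] + gap_open)
    }
  }
  score <- max(D[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])

  # traceback; ties prefer the diagonal, then consuming the reference
  map <- rep(NA_integer_, n)
  i <- n + 1L; j <- m + 1L
  state <- which.max(c(D[i, j], X[i, j], Y[i, j]))
  ncol_aln <- 0L; nmatch <- 0L
  while (i > 1L || j > 1L) {
    ncol_aln <- ncol_aln + 1L
    if (state == 1L) {
      map[i - 1L] <- j - 1L
      if (ref[i - 1L] == cln[j - 1L] ||
          (ref[i - 1L] == "C" && cln[j - 1L] == "T"))
        nmatch <- nmatch + 1L
      prev <- c(D[i - 1L, j - 1L], X[i - 1L, j - 1L], Y[i - 1L, j - 1L])
      state <- which.max(prev)
      i <- i - 1L; j <- j - 1L
    } else if (state == 2L) {
      prev <- c(D[i - 1L, j] + gap_open, X[i - 1L, j] + gap_extend,
                Y[i - 1L, j] + gap_open)
      state <- which.max(prev)
      i <- i - 1L
    } else {
      prev <- c(D[i, j - 1L] + gap_open, X[i, j - 1L] + gap_open,
                Y[i, j - 1L] + gap_extend)
      state <- if (prev[1L] >= prev[3L] && prev[1L] >= prev[2L]) 1L
               else if (prev[3L] >= prev[2L]) 3L else 2L
      j <- j - 1L
    }
  }
  identity <- if (ncol_aln) nmatch / ncol_aln else 0
  rejected <- identity < min_identity
  list(map = map, score = score, identity = identity, rejected = rejected,
       reason = if (rejected)
         sprintf("alignment identity %.3f below %.2f", identity,
                 min_identity) else NA_character_)
}

#' Call per-CpG methylation states from bisulfite clones
#'
#' Each clone is globally aligned to the reference amplicon with
#' bisulfite-aware scoring. At every CpG site, the clone base at the
#' reference C is read as: C = methylated (conversion blocked by 5mC),
#' T = unmethylated (converted), anything else or a gap = ambiguous. The
#' G of the CpG is not used. Per-clone conversion efficiency is the
#' fraction of non-CpG reference cytosines read as T; clones below
#' \code{min_conversion} (or with rejected alignments) are excluded from
#' per-sample fractions and flagged.
#'
#' @param clones a \code{clone_set}.
#' @param min_conversion conversion-efficiency QC threshold (default
#'   0.95).
#' @param min_identity alignment rejection threshold, see
#'   [align_clone()].
#' @return object of class \code{clone_call_matrix}: list with
#'   \code{calls} (clone x site character matrix, values
#'   \code{"methylated"}, \code{"unmethylated"}, \code{"ambiguous"}),
#'   \code{conversion_efficiency}, \code{retained}, \code{reason},
#'   \code{sample_id}, \code{cpg_sites}.
#' @export
call_methylation <- function(clones, min_conversion = 0.95,
                             min_identity = 0.7) {
  stopifnot(inherits(clones, "clone_set"))
  ref <- strsplit(clones$reference, "", fixed = TRUE)[[1]]
  sites1 <- clones$cpg_sites + 1L          # 1-based C positions
  nonCpG_C <- setdiff(which(ref == "C"), sites1)
  k <- nrow(clones$clones)
  calls <- matrix("ambiguous", k, length(sites1),
                  dimnames = list(clones$clones$clone_id,
                                  paste0("cpg_", clones$cpg_sites)))
  eff <- rep(NA_real_, k)
  retained <- rep(TRUE, k)
  reason <- rep(NA_character_, k)

  for (ci in seq_len(k)) {
    aln <- align_clone(clones$clones$sequence[ci], clones$reference,
                       min_identity = min_identity)
    if (aln$rejected) {
      retained[ci] <- FALSE
      reason[ci] <- aln$reason
      next
    }
    cseq <- strsplit(toupper(clones$clones$sequence[ci]), "",
                     fixed = TRUE)[[1]]
    base_at <- function(p) {
      q <- aln$map[p]
      if (is.na(q)) NA_character_ else cseq[q]
    }
    b <- vapply(sites1, base_at, character(1))
    calls[ci, ] <- ifelse(is.na(b), "ambiguous",
                          ifelse(b == "C", "methylated",
                                 ifelse(b == "T", "unmethylated",
                                        "ambiguous")))
    conv <- vapply(nonCpG_C, base_at, character(1))
    n_t <- sum(conv == "T", na.rm = TRUE)
    n_c <- sum(conv == "C", na.rm = TRUE)
    eff[ci] <- if (n_t + n_c > 0) n_t / (n_t + n_c) else NA_real_
    if (!is.na(eff[ci]) && eff[ci] < min_conversion) {
      retained[ci] <- FALSE
      reason[ci] <- sprintf("conversion efficiency %.3f below %.2f",
                            eff[ci], min_conversion)
    }
  }
  structure(list(calls = calls, conversion_efficiency = eff,
                 retained = retained, reason = reason,
                 sample_id = clones$clones$sample_id,
                 cpg_sites = clones$cpg_sites),
            class = "clone_call_matrix")
}

#' Lollipop-style per-sample summary of clone methylation calls
#'
#' Produces, for each sample, the ordered clone x CpG-site call grid (the
#' content of a lollipop plot: filled circle = methylated, open =
#' unmethylated) plus per-site and overall methylated fractions.
#' Ambiguous calls and QC-excluded clones are omitted from all
#' denominators.
#'
#' @param calls a \code{clone_call_matrix}.
#' @return list, one element per sample: \code{grid} (clone x site matrix
#'   with 1 = methylated, 0 = unmethylated, NA = ambiguous),
#'   \code{site_fraction}, \code{overall_fraction},
#'   \code{n_clones_retained}.
#' @export
lollipop_summary <- function(calls) {
  stopifnot(inherits(calls, "clone_call_matrix"))
  num <- matrix(NA_real_, nrow(calls$calls), ncol(calls$calls),
                dimnames = dimnames(calls$calls))
  num[calls$calls == "methylated"] <- 1
  num[calls$calls == "unmethylated"] <- 0
  samples <- unique(calls$sample_id)
  out <- lapply(samples, function(ss) {
    rows <- which(calls$sample_id == ss & calls$retained)
    if (!length(rows)) {
      warning("all clones rejected for sample ", ss, call. = FALSE)
      return(list(grid = num[integer(), , drop = FALSE],
                  site_fraction = rep(NA_real_, ncol(num)),
                  overall_fraction = NA_real_, n_clones_retained = 0L))
    }
    g <- num[rows, , drop = FALSE]
    list(grid = g,
         site_fraction = colMeans(g, na.rm = TRUE),
         overall_fraction = mean(g, na.rm = TRUE),
         n_clones_retained = length(rows))
  })
  names(out) <- samples
  out
}

#' Read a reference amplicon and bisulfite clones from FASTA
#'
#' The clone FASTA encodes the originating sample in the description as
#' \code{sample=<id>}. A record named \code{reference} in the clone file
#' may supply the amplicon when \code{ref_file} is NULL.
#'
#' @param clones_file FASTA of clone sequences.
#' @param ref_file FASTA holding the reference amplicon (first record
#'   used); NULL to take the \code{reference} record from
#'   \code{clones_file}.
#' @return a \code{clone_set}.
#' @export
read_clones <- function(clones_file, ref_file = NULL) {
  seqs <- Biostrings::readDNAStringSet(clones_file)
  ids <- names(seqs)
  ref_seq <- NULL
  if (is.null(ref_file)) {
    is_ref <- grepl("^reference( |$)", ids)
    if (!any(is_ref))
      stop("no reference record in ", clones_file,
           " and no ref_file given", call. = FALSE)
    ref_seq <- as.character(seqs[[which(is_ref)[1L]]])
    seqs <- seqs[!is_ref]
    ids <- names(seqs)
  } else {
    refs <- Biostrings::readDNAStringSet(ref_file)
    ref_seq <- as.character(refs[[1L]])
  }
  sample_id <- sub(".*sample=([^ ]+).*", "\\1", ids)
  sample_id[!grepl("sample=", ids)] <- "sample1"
  clone_id <- sub(" .*", "", ids)
  clone_set(ref_seq,
            data.frame(clone_id = clone_id, sample_id = sample_id,
                       sequence = as.character(seqs),
                       stringsAsFactors = FALSE))
}

#' Write a clone set (reference first) to FASTA
#'
#' @param clones a \code{clone_set}.
#' @param file output FASTA path.
#' @export
write_clones <- function(clones, file) {
  seqs <- c(clones$reference, clones$clones$sequence)
  names(seqs) <- c("reference",
                   paste0(clones$clones$clone_id, " sample=",
                          clones$clones$sample_id))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), file)
  invisible(file)
}
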