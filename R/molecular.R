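## cox1 molecular identification: FASTA I/O, haplotype dereplication and
## reference-panel matching, Kimura-2-parameter distances, neighbor-joining
## and minimum-evolution trees with bootstrap support.
##
## Sequence records travel as a plain data.frame (seq_id, sequence, species)
## so tables stay printable; Biostrings handles the FASTA format itself.

.IUPAC <- c("A", "C", "G", "T", "N", "-", "R", "Y", "S", "W", "K", "M",
            "B", "D", "H", "V", "U")

#' Build a sequence record table
#'
#' @param seq_id character ids.
#' @param sequence character DNA sequences (uppercased on ingest).
#' @param species species label per sequence: canis, orientis, felis or
#'   unknown (default).
#' @return data.frame with columns seq_id, sequence, species.
#' @export
sequenceRecords <- function(seq_id, sequence, species = "unknown") {
  sequence <- toupper(as.character(sequence))
  if (any(!nzchar(sequence))) stop("empty sequence")
  for (i in seq_along(sequence)) {
    ch <- strsplit(sequence[i], "")[[1]]
    bad <- which(!ch %in% .IUPAC)
    if (length(bad))
      stop("illegal character ", sQuote(ch[bad[1]]), " in sequence ",
           seq_id[i], " at position ", bad[1])
  }
  data.frame(seq_id = as.character(seq_id), sequence = sequence,
             species = rep_len(as.character(species), length(sequence)),
             stringsAsFactors = FALSE)
}

#' Read cox1 sequences from FASTA
#'
#' Wraps [Biostrings::readDNAStringSet()]; multi-line (wrapped) sequences
#' are concatenated. A header of the form \code{id [species=canis]} sets
#' the species label; otherwise species is "unknown".
#'
#' @param path FASTA file path.
#' @return sequence record data.frame (see [sequenceRecords()]); empty with
#'   a warning for an empty file.
#' @export
readCox1Fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (file.size(path) == 0 ||
      !any(grepl("^>", readLines(path, warn = FALSE)))) {
    warning("empty FASTA file: ", path)
    return(sequenceRecords(character(0), character(0), character(0)))
  }
  ss <- Biostrings::readDNAStringSet(path)
  headers <- names(ss)
  ids <- sub("\\s.*$", "", headers)
  sp <- rep("unknown", length(ss))
  has <- grepl("\\[species=([^]]+)\\]", headers)
  sp[has] <- sub(".*\\[species=([^]]+)\\].*", "\\1", headers[has])
  sequenceRecords(ids, as.character(ss), sp)
}

#' Write cox1 sequences to FASTA
#'
#' @param records sequence record data.frame.
#' @param path output path.
#' @param width line wrap width (default 70).
#' @return Invisibly, \code{path}.
#' @export
writeCox1Fasta <- function(records, path, width = 70L) {
  headers <- ifelse(records$species == "unknown", records$seq_id,
                    paste0(records$seq_id, " [species=", records$species, "]"))
  ss <- Biostrings::DNAStringSet(records$sequence)
  names(ss) <- headers
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

# comparison of two sequences anchored at the 5' end: overlap = min length.
# cox1 amplicons are ungapped coding fragments, so simple end-trimming is
# assumed alignment enough (an error is raised for large length differences)
.overlapIdentical <- function(a, b, min_overlap = 400L, max_len_diff = 60L) {
  la <- nchar(a); lb <- nchar(b)
  if (abs(la - lb) > max_len_diff)
    stop("sequence length difference ", abs(la - lb),
         " exceeds ", max_len_diff, " bases; full alignment is out of scope")
  ov <- min(la, lb)
  if (ov < min_overlap) return(NA)   # no call
  substr(a, 1L, ov) == substr(b, 1L, ov)
}

#' Collapse sequences into haplotypes
#'
#' Exact string identity over the comparison region defines a haplotype.
#' In \code{full_length} mode the whole sequence must match; in
#' \code{common_overlap} mode sequences are compared over their common
#' 5'-anchored overlap after end-trimming (>= \code{min_overlap} positions
#' required), so a terminal truncation does not split a haplotype. Ids are
#' assigned in decreasing count order, ties broken by first appearance.
#'
#' @param records sequence record data.frame.
#' @param mode "full_length" or "common_overlap".
#' @param min_overlap minimum comparison overlap (common_overlap mode).
#' @param id_prefix prefix for haplotype ids (default "H").
#' @return data.frame with one row per haplotype: haplotype_id, sequence
#'   (longest member as representative), count, species, matched_reference
#'   (NA until [matchReference()]), members (comma-separated seq ids).
#' @export
collapseHaplotypes <- function(records,
                               mode = c("full_length", "common_overlap"),
                               min_overlap = 400L, id_prefix = "H") {
  mode <- match.arg(mode)
  n <- nrow(records)
  if (n < 1L) stop("need at least one sequence")
  rep_seq <- character(0)       # representative (longest member so far)
  members <- list()
  for (i in seq_len(n)) {
    s <- records$sequence[i]
    hit <- 0L
    for (h in seq_along(rep_seq)) {
      same <- if (mode == "full_length") s == rep_seq[h]
              else isTRUE(.overlapIdentical(s, rep_seq[h], min_overlap))
      if (same) { hit <- h; break }
    }
    if (hit == 0L) {
      rep_seq <- c(rep_seq, s)
      members[[length(rep_seq)]] <- i
    } else {
      members[[hit]] <- c(members[[hit]], i)
      if (nchar(s) > nchar(rep_seq[hit])) rep_seq[hit] <- s
    }
  }
  counts <- lengths(members)
  ord <- order(-counts, vapply(members, min, 0L))
  species <- vapply(seq_along(members), function(h) {
    sp <- unique(records$species[members[[h]]])
    sp_known <- setdiff(sp, "unknown")
    if (length(sp_known) > 1L)
      stop("integrity error: haplotype mixes species (",
           paste(sp_known, collapse = ", "), "); members: ",
           paste(records$seq_id[members[[h]]], collapse = ", "))
    if (length(sp_known)) sp_known else "unknown"
  }, "")
  data.frame(
    haplotype_id = paste0(id_prefix, seq_along(ord)),
    sequence = rep_seq[ord],
    count = counts[ord],
    species = species[ord],
    matched_reference = NA_character_,
    members = vapply(members[ord], function(ix)
      paste(records$seq_id[ix], collapse = ","), ""),
    stringsAsFactors = FALSE)
}

#' Match haplotypes against a reference panel
#'
#' A haplotype matches a panel entry iff the two sequences are identical
#' over their common 5'-anchored overlap of at least \code{min_overlap}
#' positions; shorter overlaps give no call (with a warning). More than
#' one panel match is an ambiguity error.
#'
#' @param haps haplotype table from [collapseHaplotypes()].
#' @param panel sequence record data.frame (e.g. the 90-haplotype
#'   h1-h90 reference panel).
#' @param min_overlap minimum comparison overlap (default 400).
#' @return the haplotype table with \code{matched_reference} filled in
#'   (NA = novel haplotype).
#' @export
matchReference <- function(haps, panel, min_overlap = 400L) {
  if (nrow(panel) < 1L) stop("reference panel is empty")
  for (i in seq_len(nrow(haps))) {
    hits <- character(0)
    nocall <- FALSE
    for (j in seq_len(nrow(panel))) {
      same <- .overlapIdentical(haps$sequence[i], panel$sequence[j],
                                min_overlap)
      if (is.na(same)) { nocall <- TRUE; next }
      if (same) hits <- c(hits, panel$seq_id[j])
    }
    if (length(hits) > 1L)
      stop("ambiguity error: haplotype ", haps$haplotype_id[i],
           " matches several panel entries: ", paste(hits, collapse = ", "))
    if (length(hits) == 1L) haps$matched_reference[i] <- hits
    else if (nocall && !length(hits))
      warning("haplotype ", haps$haplotype_id[i],
              ": overlap below ", min_overlap, " with panel; no call")
  }
  haps
}

# split two sequences to their end-trimmed site matrix (character vectors)
.siteVectors <- function(a, b, max_len_diff = 60L) {
  la <- nchar(a); lb <- nchar(b)
  if (abs(la - lb) > max_len_diff)
    stop("sequence length difference exceeds ", max_len_diff, " bases")
  ov <- min(la, lb)
  list(a = strsplit(substr(toupper(a), 1, ov), "")[[1]],
       b = strsplit(substr(toupper(b), 1, ov), "")[[1]])
}

.PURINES <- c("A", "G")

# core K2P on two equal-length character vectors with site deletion
.k2pCore <- function(va, vb, strict = TRUE) {
  ok <- va %in% c("A", "C", "G", "T") & vb %in% c("A", "C", "G", "T")
  n <- sum(ok)
  if (n < 1L) stop("no comparable sites after deletion")
  va <- va[ok]; vb <- vb[ok]
  diffs <- va != vb
  ts <- sum(diffs & ((va %in% .PURINES) == (vb %in% .PURINES)))
  tv <- sum(diffs) - ts
  P <- ts / n; Q <- tv / n
  w1 <- 1 - 2 * P - Q; w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    if (strict) stop("saturation: Kimura-2 distance undefined (P = ",
                     signif(P, 3), ", Q = ", signif(Q, 3), ")")
    return(NA_real_)
  }
  -0.5 * log(w1) - 0.25 * log(w2)
}

#' Kimura two-parameter distance between two sequences
#'
#' Sites where either sequence has a gap, N or ambiguity code are deleted
#' pairwise (MEGA's default); over the retained sites, with transition
#' proportion P and transversion proportion Q, the distance is
#' d = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q) substitutions/site.
#' Sequences of unequal length are end-trimmed to their common 5'-anchored
#' region first.
#'
#' @param a,b DNA sequences (character scalars).
#' @return non-negative distance (substitutions/site); saturated pairs
#'   (log argument <= 0) raise an error.
#' @examples
#' a <- strrep("A", 100)
#' b <- paste0(strrep("G", 10), strrep("A", 90))
#' k2pDistance(a, b)   # P = 0.1, Q = 0: -0.5 log(0.8) = 0.111572
#' @export
k2pDistance <- function(a, b) {
  v <- .siteVectors(a, b)
  .k2pCore(v$a, v$b, strict = TRUE)
}

#' All-pairs Kimura-2-parameter distance matrix
#'
#' @param records sequence record data.frame (or named character vector of
#'   sequences).
#' @return symmetric matrix (substitutions/site) with taxa ids as dimnames;
#'   saturated pairs are NA with a warning.
#' @export
k2pMatrix <- function(records) {
  if (is.character(records))
    records <- sequenceRecords(
      if (is.null(names(records))) as.character(seq_along(records))
      else names(records), records)
  n <- nrow(records)
  vecs <- lapply(records$sequence, function(s)
    strsplit(toupper(s), "")[[1]])
  D <- matrix(0, n, n, dimnames = list(records$seq_id, records$seq_id))
  n_sat <- 0L
  for (i in seq_len(n)) for (j in seq_len(n)) if (i < j) {
    ov <- min(length(vecs[[i]]), length(vecs[[j]]))
    d <- .k2pCore(vecs[[i]][seq_len(ov)], vecs[[j]][seq_len(ov)],
                  strict = FALSE)
    if (is.na(d)) n_sat <- n_sat + 1L
    D[i, j] <- D[j, i] <- d
  }
  if (n_sat) warning(n_sat, " saturated pair(s) flagged as NA")
  D
}

#' Maximum within-species K2P distance
#'
#' For each species, the maximum distance over within-species pairs;
#' single-member species are reported as NA (undefined).
#'
#' @param D distance matrix from [k2pMatrix()].
#' @param species species label per taxon (in matrix order).
#' @return named numeric vector, one entry per species.
#' @export
maxIntragroupDistance <- function(D, species) {
  species <- as.character(species)
  if (length(species) != nrow(D))
    stop("species labels must match matrix rows")
  vapply(unique(species), function(sp) {
    ix <- which(species == sp)
    if (length(ix) < 2L) return(NA_real_)
    max(D[ix, ix], na.rm = TRUE)
  }, 0)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei neighbor joining (via [ape::nj()]); negative branch
#' lengths are clamped to zero. Exact on additive matrices.
#'
#' @param D symmetric distance matrix, >= 3 taxa, no NA entries.
#' @return an unrooted \code{phylo} tree.
#' @export
njTree <- function(D) {
  if (nrow(D) < 3L) stop("need at least 3 taxa")
  if (anyNA(D)) stop("distance matrix has flagged (NA) entries")
  tr <- ape::nj(stats::as.dist(D))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Minimum-evolution refinement of a tree
#'
#' Re-estimates branch lengths by ordinary least squares (non-negative,
#' via [phangorn::nnls.tree()]) and greedily accepts nearest-neighbor-
#' interchange moves while the total tree length strictly decreases,
#' stopping at a local optimum of the minimum-evolution criterion.
#'
#' @param tree starting tree (normally from [njTree()]).
#' @param D the distance matrix the tree summarizes.
#' @param max_iter cap on accepted moves (default 50).
#' @return refined \code{phylo} tree (total length <= input's OLS length).
#' @export
meRefine <- function(tree, D, max_iter = 50L) {
  dd <- stats::as.dist(D)
  ols <- function(tr) {
    fit <- phangorn::nnls.tree(dd, ape::unroot(tr), method = "unrooted")
    fit$edge.length[fit$edge.length < 0] <- 0
    fit
  }
  cur <- ols(tree)
  cur_len <- sum(cur$edge.length)
  if (length(cur$tip.label) < 4L) return(cur)   # no NNI moves possible
  for (it in seq_len(max_iter)) {
    nbrs <- phangorn::nni(cur)
    best <- NULL; best_len <- cur_len
    for (jj in seq_along(nbrs)) {
      cand <- ols(nbrs[[jj]])   # [[ restores multiPhylo tip labels
      len <- sum(cand$edge.length)
      if (len < best_len - 1e-12) { best <- cand; best_len <- len }
    }
    if (is.null(best)) break
    cur <- best; cur_len <- best_len
  }
  cur
}

# one full tree build from a character site matrix (taxa x sites)
.treeFromSites <- function(mat, refine = TRUE) {
  n <- nrow(mat)
  D <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n)) for (j in seq_len(n)) if (i < j) {
    d <- .k2pCore(mat[i, ], mat[j, ], strict = FALSE)
    D[i, j] <- D[j, i] <- d
  }
  if (anyNA(D)) return(NULL)   # saturated replicate
  tr <- njTree(D)
  if (refine) tr <- meRefine(tr, D)
  tr
}

#' Bootstrap support for the K2P minimum-evolution tree
#'
#' Builds the point-estimate tree (K2P distances, neighbor joining,
#' minimum-evolution refinement) from an alignment of equal-length
#' sequences, then resamples alignment columns with replacement
#' \code{n_reps} times, rebuilds the tree for each replicate, and reports
#' for each internal edge of the point tree the percentage of replicate
#' trees containing the same bipartition. Replicates whose distance matrix
#' saturates are skipped and counted.
#'
#' @param records sequence record data.frame; all sequences equal length,
#'   >= 4 taxa.
#' @param n_reps bootstrap replicates (default 1000).
#' @param seed integer RNG seed.
#' @param refine logical; apply [meRefine()] to every tree (default TRUE).
#' @return list with \code{tree} (point tree, supports as
#'   \code{node.label}, in percent), \code{skipped} (saturated replicate
#'   count) and \code{n_reps}.
#' @export
bootstrapSupport <- function(records, n_reps = 1000L, seed = 1L,
                             refine = TRUE) {
  n <- nrow(records)
  if (n < 4L) stop("bootstrap requires >= 4 taxa")
  lens <- nchar(records$sequence)
  if (length(unique(lens)) != 1L)
    stop("bootstrap requires an alignment of equal-length sequences")
  mat <- do.call(rbind, lapply(records$sequence, function(s)
    strsplit(toupper(s), "")[[1]]))
  rownames(mat) <- records$seq_id
  point <- .treeFromSites(mat, refine = refine)
  if (is.null(point)) stop("saturation in the point-estimate distances")
  set.seed(seed)
  reps <- vector("list", n_reps)
  skipped <- 0L
  for (r in seq_len(n_reps)) {
    cols <- sample.int(ncol(mat), replace = TRUE)
    tr <- .treeFromSites(mat[, cols, drop = FALSE], refine = refine)
    if (is.null(tr)) skipped <- skipped + 1L else reps[[r]] <- tr
  }
  reps <- Filter(Negate(is.null), reps)
  counts <- ape::prop.clades(point, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- round(100 * counts / length(reps))
  point$node.label <- as.character(support)
  # root split is not a real bipartition; leave its label empty
  point$node.label[1] <- ""
  list(tree = point, skipped = skipped, n_reps = n_reps)
}

#' Read / write trees in newick format
#'
#' Thin wrappers over [ape::read.tree()] / [ape::write.tree()]; branch
#' lengths and integer internal-node support labels round-trip.
#'
#' @param tree a \code{phylo} object.
#' @param path file path.
#' @return \code{readNewickTree} returns a \code{phylo};
#'   \code{writeNewickTree} returns the path invisibly.
#' @export
writeNewickTree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname writeNewickTree
#' @export
readNewickTree <- function(path) {
  tr <- tryCatch(suppressWarnings(ape::read.tree(path)),
                 error = function(e)
    stop("malformed newick in ", path, ": ", conditionMessage(e)))
  if (is.null(tr)) stop("malformed newick in ", path)
  tr
}

#' Write a haplotype table as TSV
#'
#' @param haps haplotype table from [collapseHaplotypes()].
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeHaplotypeTSV <- function(haps, path) {
  write.table(haps[, c("haplotype_id", "count", "species",
                       "matched_reference", "members")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
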