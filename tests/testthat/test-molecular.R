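# cox1 handling: FASTA, haplotypes, K2P distances, NJ/ME trees, bootstrap

test_that("FASTA round trip preserves ids, species tags and wrapped sequences", {
  set.seed(101)
  recs <- sequenceRecords(paste0("seq", 1:12),
                          replicate(12, random_dna(sample(550:650, 1))),
                          sample(c("canis", "orientis", "unknown"), 12, TRUE))
  tf <- withr::local_tempfile(fileext = ".fasta")
  writeCox1Fasta(recs, tf, width = 60)      # forces multi-line wrapping
  back <- readCox1Fasta(tf)
  expect_equal(back, recs)
  # empty file: empty record set with a warning
  writeLines(character(0), tf)
  expect_warning(empty <- readCox1Fasta(tf), "empty")
  expect_equal(nrow(empty), 0)
  # illegal characters rejected with a position
  expect_error(sequenceRecords("x", "ACGTZ"), "position 5")
  # lower case upcased on ingest
  expect_equal(sequenceRecords("x", "acgt")$sequence, "ACGT")
})

test_that("collapseHaplotypes groups identical sequences with ordered ids", {
  s1 <- random_dna(600, seed = 5); s2 <- random_dna(600)
  recs <- sequenceRecords(paste0("r", 1:5), c(s1, s2, s1, s1, s2), "canis")
  haps <- collapseHaplotypes(recs)
  expect_equal(nrow(haps), 2)
  expect_equal(haps$count, c(3, 2))
  expect_equal(haps$haplotype_id, c("H1", "H2"))
  expect_equal(sum(haps$count), nrow(recs))
  expect_equal(haps$members[1], "r1,r3,r4")
  # idempotent: collapsing the representatives changes nothing
  again <- collapseHaplotypes(sequenceRecords(haps$haplotype_id,
                                              haps$sequence, haps$species))
  expect_equal(nrow(again), 2)
  expect_true(all(again$count == 1))
  # mixed-species haplotype is an integrity error naming members
  bad <- sequenceRecords(c("a", "b"), c(s1, s1), c("canis", "orientis"))
  expect_error(collapseHaplotypes(bad), "a, b")
})

test_that("common_overlap mode tolerates terminal truncations", {
  s <- random_dna(620, seed = 6)
  trunc <- substr(s, 1, 610)                 # terminal 10-base truncation
  recs <- sequenceRecords(c("full", "cut"), c(s, trunc), "canis")
  expect_equal(nrow(collapseHaplotypes(recs, mode = "full_length")), 2)
  haps <- collapseHaplotypes(recs, mode = "common_overlap")
  expect_equal(nrow(haps), 1)
  expect_equal(haps$count, 2)
  expect_equal(nchar(haps$sequence), 620)    # longest member representative
  # overlap below the 400-bp floor stays separate
  short <- substr(s, 1, 399)
  recs2 <- sequenceRecords(c("full", "tiny"), c(s, short), "canis")
  expect_error(collapseHaplotypes(recs2, mode = "common_overlap"),
               "length difference")
})

test_that("matchReference finds exact panel matches and flags novelty", {
  set.seed(7)
  panel_seqs <- replicate(10, random_dna(600))
  panel <- sequenceRecords(paste0("h", 1:10), panel_seqs, "canis")
  # a haplotype equal to h4 (modulo a terminal truncation) matches it
  query <- sequenceRecords(c("q1", "q2"),
                           c(substr(panel_seqs[4], 1, 590),
                             paste0("T", substr(panel_seqs[5], 2, 600))),
                           "canis")
  haps <- matchReference(collapseHaplotypes(query), panel)
  m <- setNames(haps$matched_reference, vapply(strsplit(haps$members, ","),
                                               `[`, "", 1))
  expect_equal(m[["q1"]], "h4")
  expect_true(is.na(m[["q2"]]))              # 1 substitution away: novel
  # overlap < 400 with every panel entry: no call, with a warning
  short_panel <- sequenceRecords("h99", substr(panel_seqs[4], 1, 420),
                                 "canis")
  shortq <- collapseHaplotypes(
    sequenceRecords("s", substr(panel_seqs[4], 1, 390), "canis"))
  expect_warning(res <- matchReference(shortq, short_panel), "no call")
  expect_true(is.na(res$matched_reference))
})

test_that("k2pDistance evaluates the Kimura formula on retained sites", {
  a <- strrep("A", 100)
  expect_equal(k2pDistance(a, a), 0)
  # 10 transitions: P = 0.1, Q = 0 -> -log(0.8)/2
  b <- paste0(strrep("G", 10), strrep("A", 90))
  expect_equal(k2pDistance(a, b), -0.5 * log(0.8), tolerance = 1e-9)
  expect_equal(k2pDistance(a, b), 0.111572, tolerance = 1e-5)
  # 5 transitions + 5 transversions
  b2 <- paste0(strrep("G", 5), strrep("C", 5), strrep("A", 90))
  expect_equal(k2pDistance(a, b2), -0.5 * log(0.85) - 0.25 * log(0.9),
               tolerance = 1e-12)
  # pairwise deletion: sites with N or gaps are dropped from both P and Q
  aN <- paste0("N-", strrep("A", 98))
  bN <- paste0("GG", strrep("G", 10), strrep("A", 88))
  expect_equal(k2pDistance(aN, bN),
               {P <- 10 / 98; -0.5 * log(1 - 2 * P)}, tolerance = 1e-12)
  # saturation is an error for the scalar form
  expect_error(k2pDistance(strrep("A", 10), strrep("G", 10)), "saturation")
  expect_error(k2pDistance("NNN", "AAA"), "no comparable sites")
})

test_that("k2p agrees with an independent reference implementation", {
  skip_if_not_installed("ape")
  set.seed(110)
  for (rep in 1:5) {
    pair <- mutate_pair(runif(1, 0.02, 0.15), L = 500)
    m <- t(vapply(strsplit(tolower(pair), ""), identity, character(500)))
    rownames(m) <- c("a", "b")
    ref <- as.matrix(ape::dist.dna(ape::as.DNAbin(m), model = "K80",
                                   pairwise.deletion = TRUE))["a", "b"]
    expect_equal(k2pDistance(pair[1], pair[2]), ref, tolerance = 1e-9)
  }
})

test_that("k2pMatrix is symmetric, consistent and flags saturated pairs", {
  set.seed(111)
  base <- strsplit(random_dna(400), "")[[1]]
  recs <- sequenceRecords(paste0("t", 1:6), vapply(1:6, function(i)
    paste(fleamorph:::.mutate(base, sample(0:8, 1), sample(0:4, 1)),
          collapse = ""), ""))
  D <- k2pMatrix(recs)
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
  for (i in 1:5) for (j in (i + 1):6)
    expect_equal(D[i, j], k2pDistance(recs$sequence[i], recs$sequence[j]),
                 tolerance = 1e-12)
  # permuting the inputs permutes rows/columns consistently
  perm <- c(3, 1, 6, 2, 5, 4)
  Dp <- k2pMatrix(recs[perm, ])
  expect_equal(Dp, D[perm, perm])
  # single sequence: 1 x 1 zero matrix
  expect_equal(k2pMatrix(recs[1, ]), matrix(0, 1, 1,
               dimnames = list("t1", "t1")))
  # saturated pair flagged NA with a warning
  sat <- sequenceRecords(c("x", "y", "z"),
                         c(strrep("A", 200), strrep("G", 200),
                           random_dna(200)))
  expect_warning(Ds <- k2pMatrix(sat), "saturated")
  expect_true(is.na(Ds["x", "y"]))
})

test_that("maxIntragroupDistance takes per-species maxima", {
  D <- matrix(c(0, 1, 5, 1, 0, 2, 5, 2, 0), 3, 3)
  out <- maxIntragroupDistance(D, c("a", "a", "b"))
  expect_equal(out[["a"]], 1)
  expect_true(is.na(out[["b"]]))             # singleton group undefined
  out2 <- maxIntragroupDistance(D, c("a", "a", "a"))
  expect_equal(out2[["a"]], 5)
})

test_that("njTree matches the 3-taxon closed form and additive matrices", {
  D3 <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- njTree(D3)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  # x_a = (d_ab + d_ac - d_bc)/2 etc.
  expect_equal(bl[["a"]], 1); expect_equal(bl[["b"]], 1)
  expect_equal(bl[["c"]], 2)
  # additive 4-taxon matrix: exact topology and lengths recovered
  true_tree <- ape::read.tree(text = "((a:1,b:2):1.5,(c:3,d:1):0.5);")
  D4 <- ape::cophenetic.phylo(true_tree)
  tr4 <- njTree(D4)
  expect_equal(ape::dist.topo(ape::unroot(true_tree), ape::unroot(tr4)), 0,
               ignore_attr = TRUE)
  expect_equal(sort(tr4$edge.length), sort(c(1, 2, 3, 1, 2)),
               tolerance = 1e-12)
  # recovered tree reproduces the additive distances exactly
  expect_equal(ape::cophenetic.phylo(tr4)[rownames(D4), colnames(D4)], D4,
               tolerance = 1e-12)
  # ultrametric with two tight pairs joins the pairs
  D5 <- matrix(10, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(D5) <- 0; D5["a", "b"] <- D5["b", "a"] <- 1
  D5["c", "d"] <- D5["d", "c"] <- 1
  tr5 <- njTree(D5)
  expect_equal(ape::dist.topo(ape::unroot(tr5), ape::unroot(
    ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);"))), 0,
    ignore_attr = TRUE)
  expect_error(njTree(D3[1:2, 1:2]), "at least 3")
})

test_that("meRefine never lengthens a tree and is idle on additive input", {
  true_tree <- ape::read.tree(text = "((a:1,b:2):1.5,(c:3,d:1):0.5);")
  D4 <- ape::cophenetic.phylo(true_tree)
  nj4 <- njTree(D4)
  me4 <- meRefine(nj4, D4)
  expect_equal(sum(me4$edge.length), sum(nj4$edge.length), tolerance = 1e-9)
  expect_equal(ape::dist.topo(ape::unroot(me4), ape::unroot(nj4)), 0,
               ignore_attr = TRUE)
  # perturbed matrices: refined length <= OLS length of the NJ topology
  set.seed(120)
  for (rep in 1:5) {
    n <- 8
    pts <- matrix(runif(n * 2), n)
    D <- as.matrix(dist(pts)) + matrix(runif(n^2, 0, 0.05), n)
    D <- (D + t(D)) / 2; diag(D) <- 0
    dimnames(D) <- list(letters[1:n], letters[1:n])
    nj_t <- njTree(D)
    nj_ols <- phangorn::nnls.tree(as.dist(D), ape::unroot(nj_t),
                                  method = "unrooted")
    nj_ols$edge.length[nj_ols$edge.length < 0] <- 0
    me_t <- meRefine(nj_t, D)
    expect_lte(sum(me_t$edge.length), sum(nj_ols$edge.length) + 1e-12)
  }
})

test_that("bootstrapSupport is seeded and certain for deep splits", {
  # two deeply separated clades of 3 taxa each
  set.seed(130)
  cl1 <- random_dna(400)
  cl2_vec <- fleamorph:::.mutate(strsplit(cl1, "")[[1]], 60, 30)
  tweak <- function(s, k) paste(fleamorph:::.mutate(strsplit(s, "")[[1]],
                                                    k, 0), collapse = "")
  recs <- sequenceRecords(paste0("t", 1:6),
                          c(cl1, tweak(cl1, 2), tweak(cl1, 4),
                            paste(cl2_vec, collapse = ""),
                            tweak(paste(cl2_vec, collapse = ""), 2),
                            tweak(paste(cl2_vec, collapse = ""), 4)))
  bs1 <- bootstrapSupport(recs, n_reps = 100, seed = 11)
  bs2 <- bootstrapSupport(recs, n_reps = 100, seed = 11)
  expect_identical(ape::write.tree(bs1$tree), ape::write.tree(bs2$tree))
  sup <- as.numeric(bs1$tree$node.label[bs1$tree$node.label != ""])
  # the central deep edge must be certain; with 3-taxon clades every
  # internal edge separates the two clusters' cores
  expect_true(any(sup == 100))
  expect_equal(bs1$skipped, 0)
})

test_that("newick round trip preserves topology, lengths and supports", {
  # quoted labels with spaces parse (ape keeps the quoting convention)
  tf <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((a:0.1,b:0.2)90:0.05,(c:0.3,'d x':0.1)75:0.02,e:0.4);", tf)
  expect_length(readNewickTree(tf)$tip.label, 5)
  txt <- "((a:0.1,b:0.2)90:0.05,(c:0.3,d_x:0.1)75:0.02,e:0.4);"
  writeLines(txt, tf)
  tr <- readNewickTree(tf)
  expect_setequal(tr$tip.label, c("a", "b", "c", "d_x", "e"))
  tf2 <- withr::local_tempfile(fileext = ".nwk")
  writeNewickTree(tr, tf2)
  tr2 <- readNewickTree(tf2)
  expect_equal(ape::dist.topo(tr, tr2), 0, ignore_attr = TRUE)
  expect_equal(sort(tr2$edge.length), sort(tr$edge.length),
               tolerance = 1e-9)
  expect_setequal(tr2$node.label, tr$node.label)
  # random trees round-trip
  set.seed(140)
  for (rep in 1:5) {
    rt <- ape::rtree(7)
    writeNewickTree(rt, tf2)
    back <- readNewickTree(tf2)
    expect_equal(ape::dist.topo(ape::unroot(rt), ape::unroot(back)), 0,
                 ignore_attr = TRUE)
    expect_equal(sort(back$edge.length), sort(rt$edge.length),
                 tolerance = 1e-9)
  }
  writeLines("((a,b", tf)
  expect_error(readNewickTree(tf), "malformed|parenth")
})
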