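## Seeded synthetic-data generators emulating the structure of the study
## data: a 2-species x 2-sex flea head landmark dataset (13 landmarks from
## 5 fixed points + a 10-point head curve), cox1 haplotype sets with the
## reported multiplicity profile, an observer-confusion process for
## morphological identification, and a per-dog infestation survey.

#' Template flea-head configuration
#'
#' A 13-point template: 5 "fixed" landmarks (two of which anchor the ends
#' of the head curve) and 8 interior semilandmarks along a circular arc
#' approximating the head outline. Points 1 and 5 are the curve endpoints;
#' points 6-13 follow the arc between them at equal arc length. The
#' template is scaled to unit centroid size so effect magnitudes and noise
#' are in Procrustes units. The exact geometry is a documented fixture,
#' not an anatomical reconstruction.
#'
#' @return list with \code{points} (13 x 2), \code{provenance},
#'   \code{curve_index} (the 10 point indices along the curve, in order).
#' @export
fleaHeadTemplate <- function() {
  theta <- seq(pi / 2, 3 * pi / 2, length.out = 10)   # frontal head arc
  arc <- cbind(cos(theta), sin(theta))
  fixed <- rbind(arc[1, ],          # 1: curve start (vertex of the head)
                 c(0.45, 0.35),     # 2: eye region
                 c(0.70, 0.00),     # 3: antennal fossa
                 c(0.45, -0.35),    # 4: oral angle
                 arc[10, ])         # 5: curve end (genal margin)
  pts <- rbind(fixed, arc[2:9, ])
  pts <- sweep(pts, 2, colMeans(pts))
  pts <- pts / sqrt(sum(pts^2))
  list(points = pts,
       provenance = c(rep("fixed", 5), rep("semilandmark", 8)),
       curve_index = c(1L, 6:13, 5L))
}

# remove translation, scale and rotation components of a 2p displacement
# vector at the template, leaving a pure tangent-space direction
.shapeTangentBasisAt <- function(Tm) {
  p <- nrow(Tm)
  tvec <- as.numeric(Tm)                      # scale direction
  rvec <- as.numeric(cbind(-Tm[, 2], Tm[, 1]))  # infinitesimal rotation
  e1 <- c(rep(1, p), rep(0, p)); e2 <- c(rep(0, p), rep(1, p))
  Q <- qr.Q(qr(cbind(e1, e2, tvec, rvec)))
  function(v) {
    v <- v - Q %*% crossprod(Q, v)
    v / sqrt(sum(v^2))
  }
}

#' Simulate a two-species, two-sex landmark dataset
#'
#' Each specimen's shape is the template plus signed species, sex and
#' interaction displacements along fixed orthogonal unit tangent vectors
#' (generated from the seed), plus isotropic Gaussian landmark noise; a
#' random similarity transform (rotation, translation, scale) is then
#' applied as digitization nuisance. Defaults reproduce the study's
#' structure: group sizes (86, 26, 45, 8) for canis-F, canis-M,
#' orientis-F, orientis-M, and effect/noise magnitudes on the scale implied
#' by the published shape ANOVA (residual per-coordinate sd ~0.007
#' Procrustes units, species and sex displacements ~3-4 times that).
#'
#' @param group_sizes integer 4-vector: canis-F, canis-M, orientis-F,
#'   orientis-M (default c(86, 26, 45, 8)).
#' @param species_effect,sex_effect,interaction_effect displacement
#'   magnitudes in Procrustes units (defaults 0.024, 0.027, 0.004).
#' @param landmark_noise_sd per-coordinate Gaussian sd (default 0.007).
#' @param rotation_range,scale_range,translation_range nuisance ranges:
#'   rotation uniform on the range (radians), scale log-uniform, and
#'   translation uniform per axis.
#' @param seed integer RNG seed.
#' @return A \linkS4class{ShapeDataset} with labels (species, sex, group)
#'   and attributes \code{"effects"} (the true unit tangent vectors) and
#'   \code{"template"}.
#' @export
simulateLandmarkDataset <- function(group_sizes = c(86L, 26L, 45L, 8L),
                                    species_effect = 0.024,
                                    sex_effect = 0.027,
                                    interaction_effect = 0.004,
                                    landmark_noise_sd = 0.007,
                                    rotation_range = c(0, 2 * pi),
                                    scale_range = c(0.5, 2),
                                    translation_range = c(-1, 1),
                                    seed = 1L) {
  stopifnot(length(group_sizes) == 4L, all(group_sizes >= 0L),
            landmark_noise_sd > 0,
            species_effect >= 0, sex_effect >= 0, interaction_effect >= 0)
  set.seed(seed)
  tmpl <- fleaHeadTemplate()
  Tm <- tmpl$points
  p <- nrow(Tm)
  proj <- .shapeTangentBasisAt(Tm)
  u_sp <- proj(rnorm(2 * p))
  u_sex <- proj(rnorm(2 * p))
  u_sex <- u_sex - drop(crossprod(u_sex, u_sp)) * u_sp
  u_sex <- u_sex / sqrt(sum(u_sex^2))
  u_int <- proj(rnorm(2 * p))
  u_int <- u_int - drop(crossprod(u_int, u_sp)) * u_sp -
    drop(crossprod(u_int, u_sex)) * u_sex
  u_int <- u_int / sqrt(sum(u_int^2))

  cells <- data.frame(
    species = c("canis", "canis", "orientis", "orientis"),
    sex = c("F", "M", "F", "M"),
    n = as.integer(group_sizes))
  n <- sum(cells$n)
  coords <- array(NA_real_, c(p, 2, n))
  species <- character(n); sex <- character(n)
  i <- 0L
  for (cix in seq_len(4)) {
    s_sp <- if (cells$species[cix] == "canis") 1 else -1
    s_sex <- if (cells$sex[cix] == "F") 1 else -1
    for (k in seq_len(cells$n[cix])) {
      i <- i + 1L
      v <- as.numeric(Tm) +
        s_sp * species_effect * u_sp +
        s_sex * sex_effect * u_sex +
        s_sp * s_sex * interaction_effect * u_int +
        rnorm(2 * p, sd = landmark_noise_sd)
      shape <- matrix(v, p, 2)
      ang <- runif(1, rotation_range[1], rotation_range[2])
      R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
      sc <- exp(runif(1, log(scale_range[1]), log(scale_range[2])))
      tr <- runif(2, translation_range[1], translation_range[2])
      coords[, , i] <- sweep(sc * shape %*% R, 2, -tr)
      species[i] <- cells$species[cix]; sex[i] <- cells$sex[cix]
    }
  }
  dimnames(coords) <- list(NULL, c("x", "y"), sprintf("spec%03d", seq_len(n)))
  labels <- data.frame(species = species, sex = sex,
                       group = paste(species, sex, sep = "_"),
                       stringsAsFactors = FALSE)
  ds <- ShapeDataset(coords, labels = labels,
                     provenance = tmpl$provenance)
  attr(ds, "effects") <- list(species = u_sp, sex = u_sex,
                              interaction = u_int)
  attr(ds, "template") <- Tm
  ds
}

#' Simulated raw digitizations (5 landmarks + one curve)
#'
#' Converts a simulated 13-point dataset into raw
#' \linkS4class{LandmarkSpecimen} objects carrying 5 fixed landmarks and a
#' 10-point head-curve polyline, the form a TPS file stores. Running
#' [buildShapeDataset()] on the result reconstructs the 13-point
#' configurations (up to the small distortion of re-resampling the
#' noisy curve at equal arc length).
#'
#' @param dataset a \linkS4class{ShapeDataset} from
#'   [simulateLandmarkDataset()].
#' @return list of \linkS4class{LandmarkSpecimen}.
#' @export
asRawSpecimens <- function(dataset) {
  tmpl <- fleaHeadTemplate()
  ids <- dimnames(dataset@coords)[[3]]
  lab <- dataset@labels
  lapply(seq_len(dim(dataset@coords)[3]), function(i) {
    cfg <- dataset@coords[, , i]
    LandmarkSpecimen(ids[i],
                     landmarks = cfg[1:5, , drop = FALSE],
                     curves = list(cfg[tmpl$curve_index, , drop = FALSE]),
                     labels = c(sex = lab$sex[i],
                                species_cox1 = lab$species[i]))
  })
}

# solve the K2P transition/transversion proportions giving distance d with
# ts/tv ratio kappa: P = kappa Q, d = -1/2 log(1-2P-Q) - 1/4 log(1-2Q)
.k2pInvert <- function(d, kappa = 2) {
  if (d <= 0) return(c(P = 0, Q = 0))
  qmax <- min(1 / (2 * kappa + 1), 0.5) * 0.999
  f <- function(Q) -0.5 * log(1 - (2 * kappa + 1) * Q) -
    0.25 * log(1 - 2 * Q) - d
  Q <- stats::uniroot(f, c(1e-12, qmax), tol = 1e-14)$root
  c(P = kappa * Q, Q = Q)
}

.BASES <- c("A", "C", "G", "T")
.TS_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")

# apply n_ts transitions and n_tv transversions at distinct random sites
.mutate <- function(seq_vec, n_ts, n_tv) {
  total <- n_ts + n_tv
  if (total == 0) return(seq_vec)
  sites <- sample.int(length(seq_vec), total)
  ts_sites <- sites[seq_len(n_ts)]
  tv_sites <- setdiff(sites, ts_sites)
  seq_vec[ts_sites] <- .TS_PARTNER[seq_vec[ts_sites]]
  for (s in tv_sites) {
    from <- seq_vec[s]
    tv_opts <- if (from %in% c("A", "G")) c("C", "T") else c("A", "G")
    seq_vec[s] <- sample(tv_opts, 1)
  }
  seq_vec
}

# counts of (transitions, transversions) realizing K2P distance d on length L
.mutationCounts <- function(d, L, kappa = 2) {
  pq <- .k2pInvert(d, kappa)
  c(ts = round(unname(pq["P"]) * L), tv = round(unname(pq["Q"]) * L))
}

#' Simulate a cox1 haplotype dataset
#'
#' Generates a random ancestor, species founder sequences at the
#' between-species K2P divergence target (exact transition/transversion
#' substitution counts solved from the K2P inversion at ratio
#' \code{kappa}), radiates the requested number of haplotypes within each
#' species so the maximum within-species divergence approximates the
#' per-species target, and replicates each haplotype to its multiplicity.
#' The default design reproduces the study's published haplotype profile:
#' 22 C. canis haplotypes (counts 56, 20, 7, 2, 2, 1, 1, 7, 1, 1, 2, 1, 1,
#' 1, 1, 1, 1, 2, 1, 2, 1, 1) and 3 C. orientis haplotypes (25, 18, 10) —
#' 25 haplotypes over 166 sequences.
#'
#' @param ancestor_length sequence length (default 614, inside the
#'   550-650 bp amplicon range).
#' @param haplotype_design named list: species -> integer vector of
#'   per-haplotype multiplicities.
#' @param within_divergence named numeric: per-species maximum within-
#'   species K2P target (defaults canis 0.012, orientis 0.064).
#' @param between_divergence between-species K2P target (default 0.12).
#' @param kappa transition/transversion ratio (default 2).
#' @param seed integer RNG seed.
#' @return sequence record data.frame with attribute \code{"membership"}
#'   (true haplotype index per record) and \code{"haplotypes"} (the unique
#'   sequences per species).
#' @export
simulateCox1Dataset <- function(ancestor_length = 614L,
                                haplotype_design = list(
                                  canis = c(56L, 20L, 7L, 2L, 2L, 1L, 1L,
                                            7L, 1L, 1L, 2L, 1L, 1L, 1L, 1L,
                                            1L, 1L, 2L, 1L, 2L, 1L, 1L),
                                  orientis = c(25L, 18L, 10L)),
                                within_divergence = c(canis = 0.012,
                                                      orientis = 0.064),
                                between_divergence = 0.12,
                                kappa = 2, seed = 1L) {
  stopifnot(ancestor_length >= 100L, all(unlist(haplotype_design) >= 1L),
            between_divergence > 0, between_divergence < 0.7)
  set.seed(seed)
  L <- as.integer(ancestor_length)
  anc <- sample(.BASES, L, replace = TRUE)
  half <- .mutationCounts(between_divergence / 2, L, kappa)
  if (sum(half) < 1) stop("between-species divergence infeasible at this length")
  species <- names(haplotype_design)
  founders <- lapply(species, function(sp) .mutate(anc, half["ts"], half["tv"]))
  names(founders) <- species

  ids <- character(0); seqs <- character(0); sps <- character(0)
  membership <- integer(0)
  hap_seqs <- list()
  hap_global <- 0L
  for (sp in species) {
    mult <- haplotype_design[[sp]]
    H <- length(mult)
    d_w <- within_divergence[[sp]]
    budget <- .mutationCounts(d_w, L, kappa)
    m_half <- max(1L, as.integer(ceiling(sum(budget) / 2)))
    haps <- vector("list", H)
    haps[[1]] <- founders[[sp]]
    for (h in seq_len(H)[-1]) {
      repeat {
        # two haplotypes carry the half-budget so the max pair spans d_w;
        # the rest sit closer to the founder
        k <- if (h <= 3L) m_half else sample.int(m_half, 1)
        n_ts <- rbinom(1, k, kappa / (kappa + 1))
        cand <- .mutate(founders[[sp]], n_ts, k - n_ts)
        key <- paste(cand, collapse = "")
        if (!key %in% vapply(haps[seq_len(h - 1)],
                             function(x) paste(x, collapse = ""), ""))
          break
      }
      haps[[h]] <- cand
    }
    hap_seqs[[sp]] <- vapply(haps, paste, "", collapse = "")
    for (h in seq_len(H)) {
      hap_global <- hap_global + 1L
      reps <- mult[h]
      ids <- c(ids, sprintf("%s_h%02d_%03d", sp, h, seq_len(reps)))
      seqs <- c(seqs, rep(hap_seqs[[sp]][h], reps))
      sps <- c(sps, rep(sp, reps))
      membership <- c(membership, rep(hap_global, reps))
    }
  }
  out <- sequenceRecords(ids, seqs, sps)
  attr(out, "membership") <- membership
  attr(out, "haplotypes") <- hap_seqs
  out
}

#' Default observer confusion matrix
#'
#' Row-stochastic confusion of the traditional morphological key, built
#' from the study's published misidentification pattern: C. canis is
#' identified correctly ~92% of the time (8% called orientis), female
#' C. orientis are called canis 31% of the time and male C. orientis 57%
#' of the time, with a small indeterminate rate for all classes.
#'
#' @param indeterminate_rate probability of an indeterminate call
#'   (default 0.1, the study left 19/199 fleas unassigned).
#' @return 4 x 3 row-stochastic matrix; rows canis_F, canis_M, orientis_F,
#'   orientis_M; columns canis, orientis, indeterminate.
#' @export
observerConfusionDefault <- function(indeterminate_rate = 0.1) {
  ok <- 1 - indeterminate_rate
  m <- rbind(
    canis_F = c(0.92, 0.08, 0) * ok,
    canis_M = c(0.92, 0.08, 0) * ok,
    orientis_F = c(0.31, 0.69, 0) * ok,
    orientis_M = c(0.57, 0.43, 0) * ok)
  m[, 3] <- indeterminate_rate
  colnames(m) <- c("canis", "orientis", "indeterminate")
  m
}

#' Simulate observer (morphological key) identifications
#'
#' Independent draws per specimen from the true class's row of a
#' row-stochastic confusion matrix.
#'
#' @param truth character vector of true class labels; every label must be
#'   a row of \code{confusion}.
#' @param confusion matrix with rownames = true classes, colnames =
#'   assigned classes, rows summing to 1.
#' @param seed integer RNG seed.
#' @return character vector of assigned labels.
#' @export
simulateObserverIds <- function(truth, confusion = observerConfusionDefault(),
                                seed = 1L) {
  truth <- as.character(truth)
  if (!all(truth %in% rownames(confusion)))
    stop("confusion matrix must cover all truth classes")
  if (any(abs(rowSums(confusion) - 1) > 1e-8))
    stop("confusion rows must sum to 1")
  set.seed(seed)
  vapply(truth, function(cl)
    sample(colnames(confusion), 1, prob = confusion[cl, ]), "",
    USE.NAMES = FALSE)
}

#' Simulate a dog infestation survey
#'
#' Bernoulli infestation per dog; infested dogs carry a zero-truncated
#' geometric number of fleas; species and flea sex are drawn from the
#' composition; regions are assigned round-robin over five names.
#' Defaults match the study scale: 77 dogs, infestation probability
#' 43/77, mean flea burden ~4.6 per infested dog, species composition
#' 115:53:22:9 with the published per-species female fractions.
#'
#' @param n_dogs number of dogs (default 77).
#' @param infestation_p infestation probability (default 43/77).
#' @param composition named species probabilities (normalized internally).
#' @param female_fraction named per-species probability a flea is female.
#' @param mean_fleas mean flea count per infested dog (default 4.63).
#' @param regions region names cycled over dogs.
#' @param seed integer RNG seed.
#' @return a survey table (see [surveyTable()]).
#' @export
simulateSurvey <- function(n_dogs = 77L, infestation_p = 43 / 77,
                           composition = c(canis = 115, orientis = 53,
                                           irritans = 22, unidentified = 9),
                           female_fraction = c(canis = 88 / 115,
                                               orientis = 45 / 53,
                                               irritans = 20 / 22,
                                               unidentified = 8 / 9),
                           mean_fleas = 199 / 43,
                           regions = c("Jizzax", "Buxoro", "Fargona",
                                       "Samarkand", "Surkxandaryo"),
                           seed = 1L) {
  stopifnot(infestation_p >= 0, infestation_p <= 1, mean_fleas >= 1)
  set.seed(seed)
  composition <- composition / sum(composition)
  dog_id <- sprintf("dog%03d", seq_len(n_dogs))
  region <- rep_len(regions, n_dogs)
  age_months <- pmax(1, round(runif(n_dogs, 6, 26)))
  dog_sex <- sample(c("F", "M"), n_dogs, replace = TRUE)
  infested <- rbinom(n_dogs, 1, infestation_p) == 1
  flea_rows <- list()
  for (i in which(infested)) {
    k <- 1L + rgeom(1, 1 / mean_fleas)   # zero-truncated geometric
    sp <- sample(names(composition), k, replace = TRUE, prob = composition)
    fsex <- ifelse(runif(k) < female_fraction[sp], "F", "M")
    flea_rows[[length(flea_rows) + 1L]] <- data.frame(
      dog_id = dog_id[i], species = sp, flea_sex = fsex,
      morphology_id = NA_character_, cox1_id = sp,
      stringsAsFactors = FALSE)
  }
  fleas <- if (length(flea_rows)) do.call(rbind, flea_rows)
           else data.frame(dog_id = character(0), species = character(0),
                           flea_sex = character(0),
                           morphology_id = character(0),
                           cox1_id = character(0))
  surveyTable(dog_id, region, age_months, dog_sex, fleas)
}
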