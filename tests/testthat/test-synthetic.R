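# generators: landmark datasets, cox1 haplotype sets, observer confusion,
# infestation survey

test_that("simulateLandmarkDataset reproduces the study structure and seeds", {
  ds <- simulateLandmarkDataset(seed = 2)
  expect_equal(nSpecimens(ds), 165)
  expect_equal(nLandmarks(ds), 13)
  lab <- specimenLabels(ds)
  expect_equal(unname(table(lab$group)[c("canis_F", "canis_M",
                                         "orientis_F", "orientis_M")]),
               c(86L, 26L, 45L, 8L), ignore_attr = TRUE)
  ds2 <- simulateLandmarkDataset(seed = 2)
  expect_identical(ds@coords, ds2@coords)
  ds3 <- simulateLandmarkDataset(seed = 3)
  expect_false(identical(ds@coords, ds3@coords))
  # true effect vectors are unit-norm, orthogonal, tangent at the template
  ef <- attr(ds, "effects")
  expect_equal(sum(ef$species^2), 1)
  expect_lt(abs(sum(ef$species * ef$sex)), 1e-10)
  tmpl <- attr(ds, "template")
  expect_lt(abs(sum(ef$species * as.numeric(tmpl))), 1e-10)
})

test_that("zero effects with tiny noise collapse to the template shape", {
  ds <- simulateLandmarkDataset(group_sizes = c(5L, 5L, 5L, 5L),
                                species_effect = 0, sex_effect = 0,
                                interaction_effect = 0,
                                landmark_noise_sd = 1e-9, seed = 4)
  fit <- gpa(ds)
  expect_lt(max(fit@procrustesToMean), 1e-7)
})

test_that("group separation grows with the species effect", {
  maha <- vapply(c(0.01, 0.03, 0.09), function(eff) {
    ds <- simulateLandmarkDataset(group_sizes = c(30L, 30L, 30L, 30L),
                                  species_effect = eff, sex_effect = 0,
                                  interaction_effect = 0, seed = 11)
    fit <- gpa(ds)
    lab <- specimenLabels(fit)
    cv <- cva(tangentCoords(fit), factor(lab$species), n_perm = 0)
    cv@mahalanobis[1, 2]
  }, 0)
  expect_true(all(diff(maha) > 0))
})

test_that("raw specimens rebuild the 13-point configuration", {
  ds <- simulateLandmarkDataset(group_sizes = c(4L, 4L, 4L, 4L), seed = 9)
  raw <- asRawSpecimens(ds)
  expect_length(raw, 16)
  expect_equal(nrow(raw[[1]]@landmarks), 5)
  expect_equal(nrow(raw[[1]]@curves[[1]]), 10)
  rebuilt <- buildShapeDataset(raw)
  expect_equal(dim(rebuilt@coords), dim(ds@coords))
  # resampling the noisy curve moves semilandmarks only slightly
  expect_lt(max(abs(rebuilt@coords - ds@coords)) /
              max(abs(ds@coords)), 0.05)
  # and the full round trip survives TPS serialization
  tf <- withr::local_tempfile(fileext = ".tps")
  writeTPS(raw, tf)
  again <- buildShapeDataset(readTPS(tf))
  expect_equal(again@coords, rebuilt@coords, tolerance = 1e-9)
})

test_that("simulateCox1Dataset realizes the published haplotype profile", {
  recs <- simulateCox1Dataset(seed = 13)
  expect_equal(nrow(recs), 166)
  haps <- collapseHaplotypes(recs, id_prefix = "UZBK")
  expect_equal(nrow(haps), 25)
  expect_equal(sum(haps$count), 166)
  expect_equal(sum(haps$species == "canis"), 22)
  expect_equal(sum(haps$species == "orientis"), 3)
  expect_equal(max(haps$count), 56)
  # membership attribute partitions the records
  expect_equal(length(attr(recs, "membership")), 166)
  expect_equal(length(unique(attr(recs, "membership"))), 25)
  # reproducible given the seed
  expect_identical(recs$sequence, simulateCox1Dataset(seed = 13)$sequence)
})

test_that("small multiplicity designs collapse exactly", {
  recs <- simulateCox1Dataset(
    haplotype_design = list(canis = c(3L, 2L)), ancestor_length = 500,
    within_divergence = c(canis = 0.01), seed = 14)
  haps <- collapseHaplotypes(recs)
  expect_equal(nrow(haps), 2)
  expect_equal(haps$count, c(3, 2))
})

test_that("within-species divergence targets are approximately realized", {
  devs <- vapply(1:10, function(r) {
    recs <- simulateCox1Dataset(seed = 300 + r)
    haps <- collapseHaplotypes(recs)
    D <- k2pMatrix(sequenceRecords(haps$haplotype_id, haps$sequence,
                                   haps$species))
    maxIntragroupDistance(D, haps$species)[["orientis"]]
  }, 0)
  expect_lt(abs(mean(devs) - 0.064) / 0.064, 0.2)
  # between-species distances dominate within-species ones
  recs <- simulateCox1Dataset(seed = 21)
  haps <- collapseHaplotypes(recs)
  D <- k2pMatrix(sequenceRecords(haps$haplotype_id, haps$sequence,
                                 haps$species))
  between <- min(D[haps$species == "canis", haps$species == "orientis"])
  expect_gt(between, max(maxIntragroupDistance(D, haps$species)))
})

test_that("simulateObserverIds follows the confusion rows", {
  truth <- rep(c("canis_F", "orientis_M"), c(500, 500))
  ids <- simulateObserverIds(truth, seed = 31)
  expect_identical(ids, simulateObserverIds(truth, seed = 31))
  # identity confusion: assigned = truth
  idm <- diag(2)
  dimnames(idm) <- list(c("canis_F", "orientis_M"), c("canis_F", "orientis_M"))
  expect_identical(simulateObserverIds(truth, idm, seed = 1), truth)
  # law of large numbers at the published error rates
  om_err <- mean(ids[501:1000] == "canis")       # target 0.57 * 0.9
  expect_lt(abs(om_err - 0.57 * 0.9), 3 * sqrt(0.5 * 0.5 / 500) + 0.02)
  indet <- mean(ids == "indeterminate")          # target 0.10
  expect_lt(abs(indet - 0.1), 0.03)
  expect_error(simulateObserverIds("felis", observerConfusionDefault()),
               "cover")
})

test_that("simulateSurvey produces a consistent infestation table", {
  sv <- simulateSurvey(seed = 41)
  expect_equal(nrow(sv$dogs), 77)
  expect_equal(sort(unique(sv$dogs$region)),
               sort(c("Jizzax", "Buxoro", "Fargona", "Samarkand",
                      "Surkxandaryo")))
  expect_equal(sv$dogs$infested, sv$dogs$dog_id %in% sv$fleas$dog_id)
  # p = 1: everyone infested; singleton composition: one species
  sv1 <- simulateSurvey(n_dogs = 20, infestation_p = 1,
                        composition = c(canis = 1),
                        female_fraction = c(canis = 0.5), seed = 42)
  expect_true(all(sv1$dogs$infested))
  expect_equal(unique(sv1$fleas$species), "canis")
  # long-run prevalence matches the Bernoulli parameter
  prev <- vapply(1:40, function(r)
    mean(simulateSurvey(seed = 100 + r)$dogs$infested), 0)
  expect_lt(abs(mean(prev) - 43 / 77), 0.03)
})
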