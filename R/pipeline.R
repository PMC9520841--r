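## End-to-end pipeline runners wiring the analysis stages together with
## seeds and TSV outputs. These functions are the programmatic entry
## points; `scripts/acceptance.R` shows them driven from Rscript.

.writeTSV <- function(df, dir, name) {
  path <- file.path(dir, name)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

.writeMatrixTSV <- function(m, dir, name) {
  df <- data.frame(id = rownames(m), as.data.frame(m, check.names = FALSE),
                   check.names = FALSE)
  .writeTSV(df, dir, name)
}

#' Run the morphometric pipeline
#'
#' TPS input (or an in-memory \linkS4class{ShapeDataset}) through GPA,
#' Procrustes ANOVA (sex, species, interaction), four-group CVA with
#' permutation tests, and per-sex two-group DFA with leave-one-out
#' cross-validation. All numeric tables are written as TSV into
#' \code{out_dir}; a \code{run_log.tsv} records n, p, seed and permutation
#' counts.
#'
#' @param input path to a TPS file, a list of
#'   \linkS4class{LandmarkSpecimen}, or a \linkS4class{ShapeDataset} whose
#'   labels contain \code{species} and \code{sex}.
#' @param out_dir output directory (created if missing).
#' @param n_perm permutation rounds for CVA and DFA tests (default 10000).
#' @param seed integer RNG seed.
#' @param flip_y,apply_scale passed to [readTPS()] for file input.
#' @param ... passed to [buildShapeDataset()] for raw specimen input.
#' @return invisible list with the fitted objects (\code{gpa},
#'   \code{anova}, \code{cva}, \code{dfa_F}, \code{dfa_M}) and
#'   \code{files}.
#' @export
runMorphometrics <- function(input, out_dir, n_perm = 10000L, seed = 1L,
                             flip_y = FALSE, apply_scale = FALSE, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(input))
    input <- readTPS(input, apply_scale = apply_scale, flip_y = flip_y)
  if (is.list(input) && !is(input, "ShapeDataset")) {
    if (!length(input)) stop("empty input: no specimens")
    input <- buildShapeDataset(input, ...)
  }
  stopifnot(is(input, "ShapeDataset"))
  lab <- input@labels
  need <- c("species", "sex")
  if (!all(need %in% colnames(lab)))
    stop("morphometrics stage: labels must contain 'species' and 'sex'")
  fit <- gpa(input)
  tang <- tangentCoords(fit)
  anova_tab <- procrustesAnova(tang, lab$sex, lab$species)
  groups <- factor(paste(lab$species, lab$sex, sep = "_"))
  cva_fit <- cva(tang, groups, n_perm = n_perm, seed = seed)
  files <- character(0)
  files <- c(files, .writeTSV(
    data.frame(format(anova_tab, digits = 6)), out_dir, "procrustes_anova.tsv"))
  files <- c(files, .writeTSV(data.frame(
    specimen = rownames(cva_fit@scores),
    group = as.character(cva_fit@groups),
    format(as.data.frame(cva_fit@scores), digits = 6)),
    out_dir, "cva_scores.tsv"))
  files <- c(files, .writeTSV(data.frame(
    cv = seq_along(cva_fit@eigenvalues),
    eigenvalue = format(cva_fit@eigenvalues, digits = 6),
    percent_variance = format(cva_fit@percentVar, digits = 6)),
    out_dir, "cva_eigenvalues.tsv"))
  files <- c(files,
             .writeMatrixTSV(cva_fit@mahalanobis, out_dir,
                             "cva_mahalanobis.tsv"),
             .writeMatrixTSV(cva_fit@procrustes, out_dir,
                             "cva_procrustes.tsv"),
             .writeMatrixTSV(cva_fit@pValues$mahalanobis, out_dir,
                             "cva_p_mahalanobis.tsv"),
             .writeMatrixTSV(cva_fit@pValues$procrustes, out_dir,
                             "cva_p_procrustes.tsv"))
  dfa_fits <- list()
  for (sx in c("F", "M")) {
    sel <- lab$sex == sx
    sub <- factor(lab$species[sel])
    if (nlevels(sub) == 2L && all(table(sub) >= 3L)) {
      df_fit <- dfaTwoGroup(tang[sel, , drop = FALSE], sub,
                            n_perm = n_perm, seed = seed)
      dfa_fits[[sx]] <- df_fit
      files <- c(files, .writeMatrixTSV(
        df_fit@loo, out_dir, paste0("dfa_loo_", sx, ".tsv")))
      files <- c(files, .writeTSV(data.frame(
        statistic = c("cutoff", "permutation_p", "loo_rate_1", "loo_rate_2"),
        value = format(c(df_fit@cutoff, df_fit@permutationP,
                         df_fit@looRates), digits = 6)),
        out_dir, paste0("dfa_summary_", sx, ".tsv")))
    }
  }
  d <- dim(input@coords)
  files <- c(files, .writeTSV(data.frame(
    key = c("n", "p", "seed", "n_perm", "gpa_iterations", "gpa_converged"),
    value = c(d[3], d[1], seed, n_perm, fit@iterations, fit@converged)),
    out_dir, "run_log.tsv"))
  invisible(list(gpa = fit, anova = anova_tab, cva = cva_fit,
                 dfa_F = dfa_fits[["F"]], dfa_M = dfa_fits[["M"]],
                 files = files))
}

#' Run the molecular pipeline
#'
#' FASTA input through haplotype collapsing, optional reference-panel
#' matching, K2P distances, per-species maximum intraspecific distance and
#' the NJ/minimum-evolution tree (with bootstrap when >= 4 haplotypes).
#'
#' @param input FASTA path or a sequence record data.frame.
#' @param out_dir output directory.
#' @param panel optional reference panel (FASTA path or record data.frame).
#' @param bootstrap_reps bootstrap replicates (default 1000; 0 disables).
#' @param seed integer RNG seed.
#' @param mode haplotype comparison mode (see [collapseHaplotypes()]).
#' @return invisible list with \code{haplotypes}, \code{distances},
#'   \code{max_within}, \code{tree} and \code{files}.
#' @export
runMolecular <- function(input, out_dir, panel = NULL,
                         bootstrap_reps = 1000L, seed = 1L,
                         mode = "full_length") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(input)) input <- readCox1Fasta(input)
  if (!nrow(input)) stop("molecular stage: no sequences")
  haps <- collapseHaplotypes(input, mode = mode)
  if (!is.null(panel)) {
    if (is.character(panel)) panel <- readCox1Fasta(panel)
    haps <- matchReference(haps, panel)
  }
  D <- k2pMatrix(sequenceRecords(haps$haplotype_id, haps$sequence,
                                 haps$species))
  max_within <- maxIntragroupDistance(D, haps$species)
  files <- c(writeHaplotypeTSV(haps, file.path(out_dir, "haplotypes.tsv")),
             .writeMatrixTSV(round(D, 6), out_dir, "k2p_distances.tsv"),
             .writeTSV(data.frame(species = names(max_within),
                                  max_within_k2p = format(max_within,
                                                          digits = 6)),
                       out_dir, "max_within_distance.tsv"))
  tree <- NULL
  if (nrow(haps) >= 3L) {
    if (nrow(haps) >= 4L && bootstrap_reps > 0 &&
        length(unique(nchar(haps$sequence))) == 1L) {
      bs <- bootstrapSupport(
        sequenceRecords(haps$haplotype_id, haps$sequence, haps$species),
        n_reps = bootstrap_reps, seed = seed)
      tree <- bs$tree
    } else {
      tree <- meRefine(njTree(D), D)
    }
    files <- c(files,
               writeNewickTree(tree, file.path(out_dir, "me_tree.nwk")))
  }
  invisible(list(haplotypes = haps, distances = D,
                 max_within = max_within, tree = tree, files = files))
}

#' Run the survey statistics pipeline
#'
#' Prevalence (overall and by age/sex/region), species composition, sex
#' ratios and, when both morphology and cox1 identifications are present,
#' the identification-agreement table.
#'
#' @param survey a survey table (see [surveyTable()]) or a length-2
#'   character vector of TSV paths (dogs, fleas).
#' @param out_dir output directory.
#' @return invisible list with the computed statistics and \code{files}.
#' @export
runSurvey <- function(survey, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(survey))
    survey <- readSurveyTSV(survey[1], survey[2])
  if (!nrow(survey$dogs)) stop("survey stage: empty dog table")
  prev <- rbind(infestationByGroup(survey, "all"),
                infestationByGroup(survey, "age"),
                infestationByGroup(survey, "sex"),
                infestationByGroup(survey, "region"))
  comp <- NULL; ratios <- NULL; agree <- NULL
  if (nrow(survey$fleas)) {
    counts <- table(survey$fleas$species)
    comp <- speciesComposition(c(counts))
    ratios <- do.call(rbind, lapply(names(counts), function(sp) {
      fl <- survey$fleas[survey$fleas$species == sp, ]
      f <- sum(fl$flea_sex == "F"); m <- sum(fl$flea_sex == "M")
      data.frame(species = sp, females = f, males = m,
                 ratio = if (m >= 1) sexRatio(f, m) else NA_real_)
    }))
    ok <- !is.na(survey$fleas$morphology_id) & !is.na(survey$fleas$cox1_id)
    if (any(ok))
      agree <- agreementTable(survey$fleas$cox1_id[ok],
                              survey$fleas$morphology_id[ok])
  }
  files <- .writeTSV(prev, out_dir, "prevalence.tsv")
  if (!is.null(comp))
    files <- c(files, .writeTSV(
      data.frame(species = names(comp), percent = as.numeric(comp),
                 percent_raw = format(attr(comp, "raw"), digits = 6)),
      out_dir, "composition.tsv"))
  if (!is.null(ratios))
    files <- c(files, .writeTSV(ratios, out_dir, "sex_ratios.tsv"))
  if (!is.null(agree)) {
    files <- c(files, .writeMatrixTSV(agree$table, out_dir,
                                      "agreement_table.tsv"))
    files <- c(files, .writeTSV(
      data.frame(class = names(agree$misclassification),
                 misclassification_pct = as.numeric(agree$misclassification)),
      out_dir, "agreement_misclassification.tsv"))
  }
  invisible(list(prevalence = prev, composition = comp, sex_ratios = ratios,
                 agreement = agree, files = files))
}
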