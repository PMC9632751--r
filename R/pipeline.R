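# Pipeline orchestration: each run_*() step reads/writes the plain-CSV
# interchange formats so the whole analysis can be driven as
# simulate -> derive -> fit -> gxe -> diversity -> report, with a JSON
# provenance record per step.

config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, ascii = TRUE))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

write_provenance <- function(out_dir, step, config) {
  config <- unclass(config)
  rec <- list(step = step, config = config, config_hash = config_hash(config),
              seed = config$seed,
              r_version = as.character(getRversion()),
              package_version = as.character(utils::packageVersion("shrimpquant")),
              timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(rec, file.path(out_dir, paste0(step, "_provenance.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")
}

#' Simulate a dataset to files
#'
#' Writes `pedigree.csv`, `phenotypes.csv` (animal, pond, simulated traits),
#' `landmarks.csv`, `truth.csv` (true breeding values) plus a provenance
#' record.
#'
#' @param cfg A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @param landmarks Generate landmark files too (default TRUE).
#' @return Invisibly, the simulated dataset.
#' @export
run_simulate <- function(cfg, out_dir, landmarks = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ds <- simulate_dataset(cfg, landmarks = landmarks)
  write_pedigree(ds$pedigree, file.path(out_dir, "pedigree.csv"))
  write.csv(ds$phenotypes, file.path(out_dir, "phenotypes.csv"),
            row.names = FALSE, quote = FALSE)
  truth <- data.frame(animal_id = rownames(ds$bv), ds$bv, check.names = FALSE)
  write.csv(truth, file.path(out_dir, "truth_bv.csv"), row.names = FALSE, quote = FALSE)
  comp <- rbind(data.frame(component = "G", trait = colnames(cfg$trueG),
                           cfg$trueG, check.names = FALSE),
                data.frame(component = "R", trait = colnames(cfg$trueR),
                           cfg$trueR, check.names = FALSE))
  write.csv(comp, file.path(out_dir, "truth_components.csv"),
            row.names = FALSE, quote = FALSE)
  if (landmarks) write_landmarks(ds$landmarks, file.path(out_dir, "landmarks.csv"))
  cfg_json <- cfg
  cfg_json$trueG <- NULL; cfg_json$trueR <- NULL; cfg_json$pond_effects <- NULL
  write_provenance(out_dir, "simulate", cfg_json)
  invisible(ds)
}

#' Derive traits from landmark and phenotype files
#'
#' Reads a landmark CSV and a phenotype CSV (for body weight and pond),
#' derives the morphometric traits per animal and writes the canonical trait
#' table. Malformed landmark rows are skipped with a warning and the final
#' counts reported.
#'
#' @param landmarks_csv,phenotypes_csv Input paths.
#' @param out_csv Output trait CSV path.
#' @return Invisibly, the trait data.frame.
#' @export
run_derive <- function(landmarks_csv, phenotypes_csv, out_csv) {
  lms <- read_landmarks(landmarks_csv)
  ph <- read_delim_auto(phenotypes_csv)
  stopifnot(all(c("animal_id", "pond", "BW") %in% names(ph)))
  rows <- list(); skipped <- 0L
  for (id in names(lms)) {
    j <- match(id, as.character(ph$animal_id))
    if (is.na(j) || !is.finite(ph$BW[j]) || ph$BW[j] <= 0) {
      warning("no usable body weight for animal ", id, "; skipped", call. = FALSE)
      skipped <- skipped + 1L
      next
    }
    rows[[id]] <- derive_traits(lms[[id]], bw = ph$BW[j], pond = ph$pond[j])
  }
  out <- do.call(rbind, rows)
  message(nrow(out), " trait records written, ", skipped, " skipped")
  write_traits(out, out_csv)
  invisible(out)
}

#' Fit univariate animal models for a set of traits
#'
#' Reads trait and pedigree files, builds the relationship matrix once,
#' shares one spectral decomposition across traits, and writes a
#' variance-component report (`fit_components.csv`) and per-animal EBVs
#' (`ebv_<trait>.csv`).
#'
#' @param traits_csv,pedigree_csv Input paths.
#' @param out_dir Output directory.
#' @param traits Trait columns to fit (default: all ten).
#' @param ebv_traits Traits for which EBV tables are written (default: first
#'   of `traits`).
#' @param ... Passed to [reml_fit()].
#' @return Invisibly, a list of `uni_fit` objects.
#' @export
run_fit <- function(traits_csv, pedigree_csv, out_dir,
                    traits = setdiff(trait_columns(), c("animal_id", "pond")),
                    ebv_traits = traits[1], ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  data <- read_traits(traits_csv)
  ped <- read_pedigree(pedigree_csv)
  A <- build_A(ped)
  ids <- as.character(data$animal_id)
  sp <- spectral_prep(A, ids)
  fits <- list()
  rows <- list()
  for (tr in traits) {
    fit <- tryCatch(reml_fit(data, tr, A, sp = sp, ...), error = function(e) {
      warning("fit failed for ", tr, ": ", conditionMessage(e), call. = FALSE)
      NULL
    })
    fits[[tr]] <- fit
    if (is.null(fit)) next
    rows[[tr]] <- data.frame(
      trait = tr, n = length(fit$ids),
      sigmaA2 = fit$sigmaA2, sigmaA2_se = fit$se[1],
      sigmaE2 = fit$sigmaE2, sigmaE2_se = fit$se[2],
      h2 = fit$h2, h2_se = fit$h2_se, sigmaA = sqrt(fit$sigmaA2),
      loglik = fit$loglik, n_iter = fit$n_iter, converged = fit$converged,
      stringsAsFactors = FALSE)
  }
  write.csv(do.call(rbind, rows), file.path(out_dir, "fit_components.csv"),
            row.names = FALSE, quote = FALSE)
  for (tr in intersect(ebv_traits, names(fits))) {
    if (is.null(fits[[tr]])) next
    parents <- ped$animal[ped$founder]
    e <- blup_ebv(fits[[tr]], A, ids = c(parents, fits[[tr]]$ids))
    write.csv(e, file.path(out_dir, paste0("ebv_", tr, ".csv")),
              row.names = FALSE, quote = FALSE)
  }
  write_provenance(out_dir, "fit", list(traits = traits, seed = NA))
  invisible(fits)
}

#' Cross-pond genetic correlations for a set of traits
#'
#' Writes the long-format GxE table (`gxe_<trait>.csv`) per trait: one row per
#' pond pair with the cross-pond genetic correlation, its SE, estimability and
#' the high-SE caveat flag. Non-estimable pairs carry empty rg/se fields.
#'
#' @param traits_csv,pedigree_csv Input paths.
#' @param out_dir Output directory.
#' @param traits Traits to analyse (default `c("BW", "BL")`, representative
#'   growth traits; each pond-pair fit is a dense bivariate REML, so fitting
#'   all ten traits is possible but slow).
#' @param ... Passed to [gxe_matrix()].
#' @return Invisibly, list of [gxe_matrix()] results.
#' @export
run_gxe <- function(traits_csv, pedigree_csv, out_dir, traits = c("BW", "BL"), ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  data <- read_traits(traits_csv)
  ped <- read_pedigree(pedigree_csv)
  A <- build_A(ped)
  out <- list()
  for (tr in traits) {
    g <- gxe_matrix(data, tr, A, ped, ...)
    tab <- g$table
    write.csv(tab, file.path(out_dir, paste0("gxe_", tr, ".csv")),
              row.names = FALSE, quote = FALSE, na = "")
    out[[tr]] <- g
  }
  invisible(out)
}

#' Family diversity report files
#'
#' Writes per-pond Shannon-Wiener indices (`diversity_shannon.csv`) and the
#' sire/dam Morisita-Horn overlap matrices (`diversity_mh_sire.csv`,
#' `diversity_mh_dam.csv`).
#'
#' @param traits_csv Trait/phenotype CSV (for pond assignment).
#' @param pedigree_csv Pedigree CSV (for family membership).
#' @param out_dir Output directory.
#' @return Invisibly, the [diversity_report()] result.
#' @export
run_diversity <- function(traits_csv, pedigree_csv, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  data <- read_delim_auto(traits_csv)
  ped <- read_pedigree(pedigree_csv)
  m <- merge(data[, c("animal_id", "pond")],
             data.frame(animal_id = ped$animal, sire = ped$sire, dam = ped$dam),
             by = "animal_id")
  m <- m[!is.na(m$sire) & !is.na(m$dam), ]
  rep <- diversity_report(m)
  write.csv(rep$shannon, file.path(out_dir, "diversity_shannon.csv"),
            row.names = FALSE, quote = FALSE)
  write.csv(data.frame(pond = rownames(rep$mh$sire), rep$mh$sire, check.names = FALSE),
            file.path(out_dir, "diversity_mh_sire.csv"), row.names = FALSE, quote = FALSE)
  write.csv(data.frame(pond = rownames(rep$mh$dam), rep$mh$dam, check.names = FALSE),
            file.path(out_dir, "diversity_mh_dam.csv"), row.names = FALSE, quote = FALSE)
  invisible(rep)
}

#' Summary report tables
#'
#' Assembles the study-style summary tables from previously written pipeline
#' artifacts in `out_dir`:
#' \itemize{
#'   \item `report_trait_summary.csv` — per-trait mean/SD/CV, variance
#'     components and h2 (descriptives joined to `fit_components.csv`);
#'   \item `report_correlations.csv` — per trait pair rg/rp/re (bivariate
#'     fits) with the standardised correlated response CR and %IS;
#'   \item `report_parent_ebv_by_pond.csv` — per-pond summaries of parent
#'     EBVs for `ebv_trait`.
#' }
#' Non-estimable entries are written as empty fields, never forced numbers.
#'
#' @param traits_csv,pedigree_csv Input paths.
#' @param out_dir Directory holding earlier step outputs; report files are
#'   added there.
#' @param pair_traits Traits included in the pairwise bivariate analysis
#'   (default: all fitted traits found in `fit_components.csv`).
#' @param ebv_trait Trait for the per-pond parent EBV summary ("BL").
#' @param ... Passed to the underlying fits.
#' @return Invisibly, list of the report data.frames.
#' @export
run_report <- function(traits_csv, pedigree_csv, out_dir,
                       pair_traits = NULL, ebv_trait = "BL", ...) {
  data <- read_traits(traits_csv)
  ped <- read_pedigree(pedigree_csv)
  A <- build_A(ped)
  comp_path <- file.path(out_dir, "fit_components.csv")
  if (!file.exists(comp_path)) {
    stop("missing artifact: ", comp_path, " (run_fit must be run first)", call. = FALSE)
  }
  comp <- read.csv(comp_path, stringsAsFactors = FALSE)
  desc <- descriptives(data[, setdiff(trait_columns(), c("animal_id", "pond"))])
  summ <- merge(desc, comp, by = "trait", sort = FALSE)
  summ <- summ[match(comp$trait, summ$trait), ]
  write.csv(summ, file.path(out_dir, "report_trait_summary.csv"),
            row.names = FALSE, quote = FALSE, na = "")

  if (is.null(pair_traits)) pair_traits <- comp$trait
  ids <- as.character(data$animal_id)
  sp <- spectral_prep(A, ids)
  h2_of <- setNames(comp$h2, comp$trait)
  rows <- list()
  if (length(pair_traits) >= 2) {
    for (i in seq_along(pair_traits)[-length(pair_traits)]) {
      for (j in (i + 1):length(pair_traits)) {
        tx <- pair_traits[i]; ty <- pair_traits[j]
        fit <- tryCatch(reml_bivariate(data, c(tx, ty), A, sp = sp, ...),
                        error = function(e) NULL)
        if (is.null(fit) || !fit$correlations$rg$estimable) {
          rows[[paste(tx, ty)]] <- data.frame(
            trait_x = tx, trait_y = ty, rg = NA, rg_se = NA, rp = NA, rp_se = NA,
            re = NA, re_se = NA, CR = NA, pctIS = NA, stringsAsFactors = FALSE)
          next
        }
        co <- fit$correlations
        cr <- correlated_response(co$rg$r, h2_of[tx], h2_of[ty])
        is_ <- if (h2_of[ty] > 0) relative_efficiency(co$rg$r, h2_of[tx], h2_of[ty])
               else NA_real_
        rows[[paste(tx, ty)]] <- data.frame(
          trait_x = tx, trait_y = ty,
          rg = round(co$rg$r, 2), rg_se = signif(co$rg$se, 2),
          rp = round(co$rp$r, 2), rp_se = signif(co$rp$se, 2),
          re = round(co$re$r, 2), re_se = signif(co$re$se, 2),
          CR = round(cr, 2), pctIS = round(is_), stringsAsFactors = FALSE)
      }
    }
  }
  corr_tab <- do.call(rbind, rows)
  if (!is.null(corr_tab)) {
    write.csv(corr_tab, file.path(out_dir, "report_correlations.csv"),
              row.names = FALSE, quote = FALSE, na = "")
  }

  parents <- ped$animal[ped$founder]
  ebv_tab <- tryCatch(ebv_by_pond(data, ebv_trait, A, parents),
                      error = function(e) NULL)
  ebv_summary <- NULL
  if (!is.null(ebv_tab)) {
    sires <- grepl("^S", ebv_tab$animal_id)
    ebv_tab$parent_type <- ifelse(sires, "sire", "dam")
    agg <- aggregate(ebv ~ pond + parent_type, data = ebv_tab,
                     FUN = function(x) c(mean = mean(x), sd = sd(x),
                                         min = min(x), max = max(x)))
    ebv_summary <- do.call(data.frame, agg)
    names(ebv_summary) <- c("pond", "parent_type", "ebv_mean", "ebv_sd",
                            "ebv_min", "ebv_max")
    write.csv(ebv_summary, file.path(out_dir, "report_parent_ebv_by_pond.csv"),
              row.names = FALSE, quote = FALSE)
  }
  invisible(list(trait_summary = summ, correlations = corr_tab,
                 parent_ebv = ebv_summary))
}
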