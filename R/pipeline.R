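# End-to-end orchestration: simulate -> QC -> kinship -> REML -> scan ->
# effects -> LD -> power, driven by one structured config with an explicit
# seed, writing per-stage outputs and a manifest with md5 hashes.

.default_config <- function() {
  list(
    seed = 1,
    outdir = "fsgwas_run",
    stages = c("simulate", "qc", "kinship", "reml", "scan", "effects",
               "ld", "power"),
    paths = list(),           # genotypes/map/pedigree/phenotypes when not simulating
    design = list(),          # sim_design() overrides
    qc = list(max_missing = 0.05, max_mendel_rate = 0.05),
    kinship = list(method = "both", blend_epsilon = 0.01),
    reml = list(traits = NULL),
    scan = list(max_pcs = 5, threshold = 5e-7, window_bp = 5e6),
    ld = list(bins = 20, max_dist_bp = 1e6),
    power = list(n = 1120, ld_r2 = 0.25, qtl_var = 0.02,
                 rel_r = c(0, 0.25, 0.5), h2 = c(0.15, 0.4), alpha = 0.05)
  )
}

.validate_config <- function(config) {
  base <- .default_config()
  config <- utils::modifyList(base, config)
  known <- c("simulate", "qc", "kinship", "reml", "scan", "effects", "ld",
             "power")
  if (identical(config$stages, "all")) config$stages <- known
  bad <- setdiff(config$stages, known)
  assert_that(!length(bad), sprintf("unknown stage(s): %s",
                                    paste(bad, collapse = ", ")))
  if (length(intersect(config$stages, c("reml", "scan", "effects")))) {
    assert_that("kinship" %in% config$stages,
                "stages reml/scan/effects require the kinship stage")
  }
  if (!"simulate" %in% config$stages &&
      length(intersect(config$stages, c("qc", "kinship", "reml", "scan",
                                        "effects", "ld")))) {
    need <- c("genotypes", "map", "pedigree", "phenotypes")
    for (nm in need) {
      pth <- config$paths[[nm]]
      assert_that(!is.null(pth), sprintf("config$paths$%s is required", nm))
      assert_that(file.exists(pth), sprintf("input file not found: %s", pth))
    }
  }
  assert_that(is.numeric(config$seed) && length(config$seed) == 1,
              "config$seed must be one integer")
  config
}

.hash_files <- function(paths) {
  h <- tools::md5sum(paths)
  setNames(unname(h), basename(paths))
}

#' Run the full analysis pipeline from a config
#'
#' Executes the requested stages in dependency order under a single explicit
#' seed. Each stage writes its outputs under `outdir` and records a manifest
#' entry (stage, parameters, output md5 hashes); identical config + seed
#' yields identical output hashes. Config validation (including existence of
#' all referenced input files) happens before any stage runs; a stage
#' failure halts the run with a diagnostic naming the stage.
#'
#' @param config A config list or the path to a YAML file. See
#'   `fsgwas:::.default_config()` for the recognized fields and defaults.
#' @return The manifest (list, one entry per executed stage), invisibly
#'   also written to `outdir/manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    assert_that(file.exists(config), sprintf("config file not found: %s",
                                             config))
    config <- yaml::read_yaml(config)
  }
  config <- .validate_config(config)
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  note <- function(stage, params, files) {
    manifest[[stage]] <<- list(stage = stage, params = params,
                               outputs = as.list(.hash_files(files)))
  }
  run_stage <- function(stage, fn) {
    tryCatch(fn(), error = function(e)
      abort(sprintf("pipeline stage '%s' failed: %s", stage,
                    conditionMessage(e))))
  }

  st <- config$stages
  pop <- NULL; g <- NULL; ped <- NULL; phen <- NULL
  fits <- list(); Gmat <- NULL; Amat <- NULL; scans <- list()

  if ("simulate" %in% st) {
    run_stage("simulate", function() {
      design <- do.call(sim_design, config$design)
      pop <<- sim_population(design, trait_architecture(),
                             seed = config$seed)
      f_g <- file.path(outdir, "genotypes.tsv")
      f_v <- file.path(outdir, "genotypes.vcf")
      f_p <- file.path(outdir, "pedigree.tsv")
      f_y <- file.path(outdir, "phenotypes.tsv")
      write_genotypes(pop$genotypes, f_g, "tabular")
      write_genotypes(pop$genotypes, f_v, "vcf")
      write_pedigree(pop$pedigree, f_p)
      write_phenotypes(pop$phenotypes, f_y)
      g <<- pop$genotypes; ped <<- pop$pedigree; phen <<- pop$phenotypes
      note("simulate", config$design,
           c(f_g, sub("(\\.tsv)?$", ".map.tsv", f_g), f_v, f_p, f_y))
    })
  } else if (length(intersect(st, c("qc", "kinship", "reml", "scan",
                                    "effects", "ld")))) {
    g <- read_genotypes(config$paths$genotypes, "tabular",
                        map_path = config$paths$map)
    ped <- read_pedigree(config$paths$pedigree)
    phen <- read_phenotypes(config$paths$phenotypes)
  }

  if ("qc" %in% st) {
    run_stage("qc", function() {
      g <<- qc_filter(g, ped, config$qc$max_missing,
                      config$qc$max_mendel_rate)
      g <<- impute_missing(g)
      f_r <- file.path(outdir, "qc_report.json")
      jsonlite::write_json(qc_report(g), f_r, digits = NA)
      note("qc", config$qc, f_r)
    })
  }

  if ("kinship" %in% st) {
    run_stage("kinship", function() {
      if (anyNA(g$dosages)) g <<- impute_missing(g)
      g <<- filter_monomorphic(g)
      Gmat <<- blend_kinship(vanraden_G(g), config$kinship$blend_epsilon)
      Amat <<- pedigree_A(ped)
      f_c <- file.path(outdir, "kinship_comparison.tsv")
      ids <- intersect(rownames(Amat), rownames(Gmat))
      cmp <- compare_A_G(kinship_matrix(unclass(Amat)[ids, ids], "pedigree_A"),
                         kinship_matrix(unclass(Gmat)[ids, ids], "blended"))
      readr::write_tsv(cmp, f_c, progress = FALSE)
      note("kinship", config$kinship, f_c)
    })
  }

  traits <- config$reml$traits %||% setdiff(names(phen %||% tibble()), "id")

  if ("reml" %in% st) {
    run_stage("reml", function() {
      res <- purrr::map_dfr(traits, function(tr) {
        y <- setNames(phen[[tr]], phen$id)
        fit <- reml_fit(y, Gmat)
        fits[[tr]] <<- fit
        dplyr::bind_cols(tibble(trait = tr), glance(fit))
      })
      f <- file.path(outdir, "reml.tsv")
      readr::write_tsv(res, f, progress = FALSE)
      f_b <- file.path(outdir, "blup.tsv")
      blups <- purrr::map_dfr(traits, function(tr)
        dplyr::bind_cols(tibble(trait = tr), blup_values(fits[[tr]])))
      readr::write_tsv(blups, f_b, progress = FALSE)
      note("reml", config$reml, c(f, f_b))
    })
  }

  if ("scan" %in% st) {
    run_stage("scan", function() {
      pcs <- pca_genotypes(subset_genotypes(g, phen$id),
                           k = max(config$scan$max_pcs, 1))
      files <- character(0)
      for (tr in traits) {
        y <- setNames(phen[[tr]], phen$id)
        npc <- select_pcs_bic(y, Gmat, pcs, config$scan$max_pcs)
        sc <- emmax_scan(y, Gmat, g, n_pcs = as.integer(npc), pcs = pcs,
                         threshold = config$scan$threshold)
        scans[[tr]] <<- sc
        f <- file.path(outdir, sprintf("scan_%s.tsv", tr))
        readr::write_tsv(as_tibble(sc), f, progress = FALSE)
        f_q <- file.path(outdir, sprintf("qq_%s.tsv", tr))
        readr::write_tsv(qq_data(sc), f_q, progress = FALSE)
        files <- c(files, f, f_q)
      }
      note("scan", config$scan[c("max_pcs", "threshold")], files)
    })
  }

  if ("effects" %in% st) {
    run_stage("effects", function() {
      files <- character(0)
      bks <- list()
      for (tr in traits) {
        fit <- fits[[tr]] %||% reml_fit(setNames(phen[[tr]], phen$id), Gmat)
        ase <- backsolve_ase(blup_values(fit), g, Gmat)
        f <- file.path(outdir, sprintf("ase_%s.tsv", tr))
        readr::write_tsv(as_tibble(ase), f, progress = FALSE)
        bks[[tr]] <- lg_decompose(ase, g)
        files <- c(files, f)
      }
      if (length(traits) >= 2) {
        pairs <- utils::combn(traits, 2, simplify = FALSE)
        rg <- purrr::map_dfr(pairs, function(pr)
          dplyr::bind_cols(tibble(trait_a = pr[1], trait_b = pr[2]),
                           lg_genetic_correlations(bks[[pr[1]]],
                                                   bks[[pr[2]]])))
        f_r <- file.path(outdir, "lg_genetic_correlations.tsv")
        readr::write_tsv(rg, f_r, progress = FALSE)
        files <- c(files, f_r)
      }
      note("effects", list(), files)
    })
  }

  if ("ld" %in% st) {
    run_stage("ld", function() {
      prof <- decay_profile(g, bins = config$ld$bins,
                            max_dist_bp = config$ld$max_dist_bp)
      f <- file.path(outdir, "ld_profile.tsv")
      readr::write_tsv(prof, f, progress = FALSE)
      note("ld", config$ld, f)
    })
  }

  if ("power" %in% st) {
    run_stage("power", function() {
      pw <- do.call(power_grid, config$power)
      f <- file.path(outdir, "power.tsv")
      readr::write_tsv(pw, f, progress = FALSE)
      note("power", config$power, f)
    })
  }

  f_m <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, f_m, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}
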