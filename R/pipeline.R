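#' Validate a set of pipeline input files
#'
#' Schema, label-set, and cross-file consistency checks. Issues are
#' reported, never thrown: the return value is a data frame with one row per
#' issue (`severity` "error"/"warning", `stage`, `message`), empty when the
#' inputs are consistent.
#'
#' @param paths Named list of file paths; recognized names are
#'   `prey_traits`, `diet_records`, `category_importances`, `measurements`,
#'   `tree`.
#' @return Data frame of issues (possibly zero rows).
#' @export
validate_inputs <- function(paths) {
  issues <- list()
  note <- function(severity, stage, message) {
    issues[[length(issues) + 1L]] <<- data.frame(
      severity = severity, stage = stage, message = message,
      stringsAsFactors = FALSE)
  }
  known <- c("prey_traits", "diet_records", "category_importances",
             "measurements", "tree")
  paths <- paths[intersect(names(paths), known)]
  paths <- Filter(function(p) is.character(p) && length(p) == 1L, paths)
  for (nm in names(paths)) {
    if (!file.exists(paths[[nm]])) note("error", nm, paste("file not found:", paths[[nm]]))
  }
  done <- function() {
    if (length(issues)) do.call(rbind, issues) else
      data.frame(severity = character(0), stage = character(0),
                 message = character(0))
  }
  ok <- function(nm) !is.null(paths[[nm]]) && file.exists(paths[[nm]])

  traits <- NULL
  if (ok("prey_traits")) {
    df <- utils::read.csv(paths$prey_traits, check.names = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    bad <- which(!(m == 0 | m == 1) | is.na(m), arr.ind = TRUE)
    if (nrow(bad)) {
      note("error", "prey_traits",
           sprintf("non-binary cell at row %d ('%s'), column '%s'",
                   bad[1L, 1L], df[[1L]][bad[1L, 1L]], colnames(m)[bad[1L, 2L]]))
    } else {
      traits <- m
      rownames(traits) <- df[[1L]]
    }
  }
  diet_species <- NULL
  if (ok("diet_records")) {
    rec <- tryCatch(read_diet_records(paths$diet_records), error = function(e) e)
    if (inherits(rec, "error")) {
      note("error", "diet_records", conditionMessage(rec))
    } else {
      diet_species <- unique(rec$species)
      if (!is.null(traits)) {
        orphan <- setdiff(unique(rec$prey_item), rownames(traits))
        if (length(orphan))
          note("error", "diet_records",
               paste("prey items not in trait matrix:", paste(orphan, collapse = ", ")))
      }
    }
  }
  if (ok("category_importances")) {
    ci <- read_category_importances(paths$category_importances)
    diet_species <- unique(c(diet_species, rownames(ci$importances)))
  }
  meas_species <- NULL
  if (ok("measurements")) {
    mm <- utils::read.csv(paths$measurements)
    if (!"species" %in% names(mm)) {
      note("error", "measurements", "missing 'species' column")
    } else meas_species <- unique(mm$species)
  }
  if (ok("tree")) {
    tr <- tryCatch(ape::read.tree(paths$tree), error = function(e) e)
    if (inherits(tr, "error") || is.null(tr)) {
      note("error", "tree", "could not parse Newick file")
    } else {
      for (set in list(diet = diet_species, measurements = meas_species)) {
        if (is.null(set)) next
        missing_tip <- setdiff(set, tr$tip.label)
        if (length(missing_tip))
          note("warning", "tree",
               paste("species absent from tree:", paste(missing_tip, collapse = ", ")))
      }
    }
  }
  if (!is.null(diet_species) && !is.null(meas_species)) {
    d <- setdiff(diet_species, meas_species)
    if (length(d))
      note("warning", "measurements",
           paste("diet species without measurements:", paste(d, collapse = ", ")))
  }
  done()
}

#' Run the full diet-and-morphology pipeline
#'
#' Executes the analysis stages in dependency order: prey-trait clustering
#' and category selection; diet aggregation and primary-diet assignment;
#' functional-character computation; and, when a tree is supplied, the
#' comparative stage (PCA + broken-stick retention, phylomorphospace,
#' phylogenetic MANOVA per grouping, Mk ancestral reconstruction,
#' discriminant re-classification). A stage whose inputs are missing or
#' invalid is recorded as failed with a stage-tagged error while independent
#' stages still complete.
#'
#' @param config Named list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{prey_traits}{path to the prey-trait CSV.}
#'     \item{diet_records}{path to long-format diet records, or}
#'     \item{category_importances}{path to a species x category table.}
#'     \item{measurements}{optional path to specimen measurements.}
#'     \item{tree}{optional path to a Newick tree.}
#'     \item{dialect, k, k_max, tie_rule, nsim, seed}{stage options;
#'       `k = "auto"` (default) selects k from the WGSS elbow,
#'       `nsim` defaults to 1000.}
#'     \item{out}{optional output directory for CSV/JSON artifacts.}
#'   }
#' @return Object of class `dietmorph_run`: list with `report` (stage
#'   results), `status` (per-stage "ok"/"failed"/"skipped" + messages) and
#'   `manifest` (config snapshot, input checksums, seeds, versions, output
#'   paths).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_validation("reading YAML configs requires the 'yaml' package")
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(list(dialect = "sqrt", k = "auto", k_max = NULL,
                                tie_rule = "rare", nsim = 1000L, seed = 1L,
                                out = NULL), config)
  status <- list()
  report <- list()
  fail <- function(stage, e) {
    status[[stage]] <<- list(state = "failed",
                             message = paste0("[", stage, "] ", conditionMessage(e)))
  }
  done <- function(stage) status[[stage]] <<- list(state = "ok", message = "")
  skip <- function(stage, why) status[[stage]] <<- list(state = "skipped", message = why)

  categories <- NULL
  tryCatch({
    if (is.null(cfg$prey_traits)) stop_validation("no prey_traits input")
    m <- read_prey_traits(cfg$prey_traits)
    pc <- prey_cluster(m, dialect = cfg$dialect)
    kmax <- cfg$k_max %||% min(nrow(m) - 1L, 15L)
    curve <- wgss_curve(m, pc, k_max = kmax)
    sel <- select_k(curve)
    k <- if (identical(cfg$k, "auto")) sel$k else as.integer(cfg$k)
    categories <- cut_categories(pc, k)
    report$prey <- list(dialect = cfg$dialect, k_selected = sel$k, k_used = k,
                        wgss = curve, membership = as.data.frame(categories))
    done("prey")
  }, error = function(e) fail("prey", e))

  cat_imp <- NULL; meta <- NULL
  tryCatch({
    if (!is.null(cfg$diet_records)) {
      if (is.null(categories)) stop_validation("prey stage did not produce categories")
      rec <- read_diet_records(cfg$diet_records)
      prof <- aggregate_importances(rec)
      cat_imp <- categorize_profile(prof, categories)
    } else if (!is.null(cfg$category_importances)) {
      ci <- read_category_importances(cfg$category_importances)
      cat_imp <- ci$importances
      meta <- ci$meta
    } else stop_validation("no diet input")
    assignment <- assign_diet(cat_imp, tie_rule = cfg$tie_rule)
    conc <- concentration_summary(cat_imp, assignment)
    report$diet <- list(assignment = as.data.frame(assignment),
                        category_counts = as.list(conc$category_counts),
                        n_concentrated = conc$n_concentrated,
                        n_unconcentrated = conc$n_unconcentrated,
                        focal = conc$focal,
                        focal_counts = conc$focal_counts)
    done("diet")
  }, error = function(e) fail("diet", e))

  zc <- NULL
  tryCatch({
    if (is.null(cfg$measurements)) {
      skip("morphology", "no measurements input")
    } else {
      mm <- utils::read.csv(cfg$measurements, stringsAsFactors = FALSE)
      chars <- functional_characters(mm)
      zc <- z_transform(chars)
      report$morphology <- list(characters = chars)
      done("morphology")
    }
  }, error = function(e) fail("morphology", e))

  tryCatch({
    if (is.null(cfg$tree) && is.null(zc)) {
      skip("comparative", "no tree / no morphology")
    } else {
      if (is.null(cfg$tree)) stop_validation("comparative stage requested without a tree")
      if (is.null(zc)) stop_validation("comparative stage requires morphology")
      tree <- ape::read.tree(cfg$tree)
      pca <- morpho_pca(zc)
      keep <- retain_axes(pca$var_frac)
      axes <- if (length(keep)) keep else 1:2
      pms <- phylomorphospace_data(tree, pca$scores, axes = axes)
      groupings <- list()
      if (!is.null(report$diet))
        groupings$synthetic <- stats::setNames(report$diet$assignment$category,
                                               report$diet$assignment$species)
      if (!is.null(meta) && "habitat" %in% names(meta))
        groupings$habitat <- stats::setNames(meta$habitat, meta$species)
      if (!is.null(meta) && "coarse_category" %in% names(meta))
        groupings$coarse <- stats::setNames(meta$coarse_category, meta$species)
      manovas <- list(); asrs <- list()
      for (g in names(groupings)) {
        gr <- groupings[[g]]
        fit <- suppressWarnings(
          phylo_manova(tree, zc, gr, nsim = cfg$nsim, seed = cfg$seed))
        manovas[[g]] <- list(lambda = fit$lambda, p_value = fit$p_value,
                             nsim = fit$nsim, seed = cfg$seed)
        common <- intersect(tree$tip.label, names(gr))
        tr2 <- ape::keep.tip(tree, common)
        a <- asr_mk1(tr2, gr[common])
        asrs[[g]] <- list(q = a$q, logLik = a$logLik,
                          transitions = asr_transitions(a))
      }
      dfa <- NULL
      if (!is.null(groupings$synthetic)) {
        common <- intersect(rownames(zc), names(groupings$synthetic))
        dfa_fit <- lda_diet(zc[common, , drop = FALSE], groupings$synthetic[common])
        dfa <- list(accuracy = dfa_fit$accuracy,
                    confusion = as.data.frame.matrix(dfa_fit$confusion),
                    mismatches = dfa_fit$mismatches)
      }
      report$comparative <- list(
        var_frac = pca$var_frac, retained_axes = keep,
        node_scores = pms$nodes, manova = manovas, asr = asrs, dfa = dfa)
      done("comparative")
    }
  }, error = function(e) fail("comparative", e))

  inputs <- cfg[intersect(names(cfg), c("prey_traits", "diet_records",
                                        "category_importances", "measurements",
                                        "tree"))]
  checksums <- vapply(inputs, function(p)
    if (file.exists(p)) unname(tools::md5sum(p)) else NA_character_,
    character(1L))
  manifest <- list(config = cfg[setdiff(names(cfg), "out")],
                   input_checksums = as.list(checksums),
                   seed = cfg$seed,
                   versions = list(
                     dietmorph = as.character(utils::packageVersion("dietmorph")),
                     R = paste(R.version$major, R.version$minor, sep = ".")),
                   outputs = character(0))
  run <- structure(list(report = report, status = status, manifest = manifest),
                   class = "dietmorph_run")
  if (!is.null(cfg$out)) run <- write_run(run, cfg$out)
  run
}

#' Write pipeline artifacts to a directory
#'
#' Writes the category membership and diet assignment CSVs and a
#' machine-readable JSON report; deterministic fields serialize
#' byte-identically across runs with the same config and seed.
#'
#' @param run A `dietmorph_run`.
#' @param dir Output directory (created if needed).
#' @return The run, with `manifest$outputs` filled in, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  if (!is.null(run$report$prey)) {
    f <- file.path(dir, "prey_categories.csv")
    utils::write.csv(run$report$prey$membership, f, row.names = FALSE)
    outputs <- c(outputs, f)
  }
  if (!is.null(run$report$diet)) {
    f <- file.path(dir, "diet_assignment.csv")
    utils::write.csv(run$report$diet$assignment, f, row.names = FALSE)
    outputs <- c(outputs, f)
  }
  f <- file.path(dir, "report.json")
  rep <- run$report
  rep$status <- lapply(run$status, function(s) s[c("state", "message")])
  rep$manifest <- run$manifest[c("input_checksums", "seed", "versions")]
  jsonlite::write_json(rep, f, auto_unbox = TRUE, digits = 12, pretty = TRUE,
                       dataframe = "rows")
  outputs <- c(outputs, f)
  run$manifest$outputs <- outputs
  invisible(run)
}

#' @export
print.dietmorph_run <- function(x, ...) {
  cat("dietmorph pipeline run\n")
  for (nm in names(x$status)) {
    cat(sprintf("  %-12s %s %s\n", nm, x$status[[nm]]$state,
                x$status[[nm]]$message))
  }
  invisible(x)
}
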