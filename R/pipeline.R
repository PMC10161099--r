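#' Pipeline run configuration
#'
#' Describes a reproducible end-to-end run: which stages to execute, where
#' to write artifacts, the master seed, and the stage parameters. Every
#' stochastic stage derives its seed deterministically from the master seed,
#' so an identical configuration reproduces every artifact bit-identically.
#'
#' Available stages, in dependency order:
#' \describe{
#'   \item{`simulate_images`}{Generate micrographs + ground-truth sidecars.}
#'   \item{`quantify`}{Per-image counts and replicate-level averages from
#'     the TIFFs.}
#'   \item{`simulate_curves`}{Per-compound TNS titration tables.}
#'   \item{`fit_pka`}{Apparent-pKa fits of the titration tables.}
#'   \item{`simulate_panel`}{Two-mechanism well panel.}
#'   \item{`mechanism`}{Per-compound disruption regressions on the panel.}
#'   \item{`correlate`}{Compound summary + correlations with
#'     phospholipidosis.}
#' }
#'
#' @param out_dir Output directory.
#' @param stages Character vector of stages to run (non-empty subset of the
#'   above).
#' @param seed Master integer seed.
#' @param images List: `n` images, `images_per_replicate`, and `args` passed
#'   on to [simulate_micrograph()].
#' @param quant A [quant_config()].
#' @param compounds Compound parameter table (see
#'   [simulate_compound_library()]); defaults to
#'   `simulate_compound_library(seed = seed)`.
#' @param titration List of extra arguments for [simulate_titration()]
#'   (`background`, `maximum`, `ph_grid`, `noise_sd`).
#' @param panel List of [panel_spec()] arguments other than `compounds` and
#'   `seed`.
#' @return A list of class `run_config`.
#' @seealso [run_pipeline()]
#' @export
run_config <- function(out_dir,
                       stages = c("simulate_images", "quantify",
                                  "simulate_curves", "fit_pka",
                                  "simulate_panel", "mechanism", "correlate"),
                       seed = 1,
                       images = list(n = 3, images_per_replicate = 3,
                                     args = list()),
                       quant = quant_config(),
                       compounds = NULL,
                       titration = list(background = 10, maximum = 1000,
                                        ph_grid = seq(3, 10, 0.5),
                                        noise_sd = 5),
                       panel = list(wells_per_compound = 15,
                                    blocker_fraction = 0.2,
                                    uptake_mean = 15, uptake_sd = 5,
                                    noise_sd = 0.1)) {
  known <- c("simulate_images", "quantify", "simulate_curves", "fit_pka",
             "simulate_panel", "mechanism", "correlate")
  if (length(stages) == 0) stop_bad_input("`stages` must not be empty.")
  unknown <- setdiff(stages, known)
  if (length(unknown) > 0) {
    stop_bad_input(sprintf("Unknown stage(s): %s.", paste(unknown, collapse = ", ")))
  }
  seed <- as.integer(seed)
  compounds <- compounds %||% simulate_compound_library(seed = seed)
  structure(
    list(out_dir = out_dir, stages = known[known %in% stages], seed = seed,
         images = utils::modifyList(
           list(n = 3, images_per_replicate = 3, args = list()), images),
         quant = quant,
         compounds = tibble::as_tibble(compounds),
         titration = titration, panel = panel),
    class = "run_config"
  )
}

#' Run the analysis pipeline
#'
#' Executes the configured stages in dependency order, logging each to
#' stderr, and writes a `manifest.json` listing every artifact with its MD5
#' content hash. Identical configurations (including the seed) produce
#' identical manifests. A stage that fails removes its partial outputs
#' before the error propagates; a stage whose input artifact is absent
#' raises an error naming the stage and the missing file.
#'
#' @param config A [run_config()].
#' @param quiet Suppress progress messages?
#' @return Invisibly, the manifest tibble (`file`, `md5`); `file` paths are
#'   relative to `config$out_dir`.
#' @examples
#' \donttest{
#' cfg <- run_config(tempfile("run"), stages = c("simulate_panel", "mechanism",
#'                                               "correlate"), seed = 42)
#' manifest <- run_pipeline(cfg)
#' }
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (!inherits(config, "run_config")) stop_bad_input("`config` must be a run_config.")
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  written <- character(0)

  run_stage <- function(stage, fn) {
    stage_files <- character(0)
    note <- function(f) stage_files <<- c(stage_files, f)
    tryCatch(
      fn(note),
      error = function(e) {
        unlink(stage_files)
        rlang::abort(sprintf("Stage '%s' failed: %s", stage, conditionMessage(e)),
                     parent = e, class = class(e)[1])
      }
    )
    written <<- c(written, stage_files)
  }

  need <- function(stage, path) {
    if (!file.exists(path)) {
      stop_bad_input(sprintf("Stage '%s' is missing its input file: %s", stage, path))
    }
    path
  }

  img_dir <- file.path(out, "images")

  for (stage in config$stages) {
    say("stage %s (seed %d)", stage, config$seed)
    switch(stage,
      simulate_images = run_stage(stage, function(note) {
        n <- config$images$n
        per_rep <- config$images$images_per_replicate
        for (i in seq_len(n)) {
          args <- config$images$args
          args$seed <- config$seed + i * 7919L
          args$well_id <- sprintf("img%02d", i)
          sc <- do.call(simulate_micrograph, args)
          note(write_micrograph(sc$micrograph, img_dir,
                                prefix = args$well_id, truth = sc$truth))
          rep_id <- sprintf("rep%02d", (i - 1) %/% per_rep + 1)
          idx_path <- file.path(img_dir, "index.csv")
          row <- tibble::tibble(prefix = args$well_id, replicate_id = rep_id)
          if (file.exists(idx_path) && i > 1) {
            idx <- dplyr::bind_rows(read_pipeline_csv(idx_path), row)
          } else idx <- row
          write_pipeline_csv(idx, idx_path)
          note(idx_path)
        }
      }),
      quantify = run_stage(stage, function(note) {
        idx <- read_pipeline_csv(need(stage, file.path(img_dir, "index.csv")))
        counts <- purrr::map_dfr(seq_len(nrow(idx)), function(i) {
          mg <- read_micrograph(img_dir, idx$prefix[i])
          quantify_image(mg$micrograph, config$quant) |>
            dplyr::mutate(replicate_id = idx$replicate_id[i])
        })
        p1 <- file.path(out, "image_counts.csv")
        write_pipeline_csv(counts, p1); note(p1)
        p2 <- file.path(out, "replicates.csv")
        write_pipeline_csv(aggregate_replicates(counts, "replicate_id"), p2)
        note(p2)
      }),
      simulate_curves = run_stage(stage, function(note) {
        curves <- purrr::map_dfr(seq_len(nrow(config$compounds)), function(i) {
          cmp <- config$compounds[i, ]
          args <- config$titration
          args$pka <- cmp$pka
          args$seed <- config$seed + i * 104729L
          dplyr::mutate(do.call(simulate_titration, args),
                        compound = cmp$compound, .before = 1)
        })
        p <- file.path(out, "titrations.csv")
        write_pipeline_csv(curves, p); note(p)
      }),
      fit_pka = run_stage(stage, function(note) {
        curves <- read_pipeline_csv(need(stage, file.path(out, "titrations.csv")))
        p <- file.path(out, "pka_fits.csv")
        write_pipeline_csv(fit_pka_panel(curves), p); note(p)
      }),
      simulate_panel = run_stage(stage, function(note) {
        spec <- do.call(panel_spec, c(list(compounds = config$compounds,
                                           seed = config$seed), config$panel))
        p <- file.path(out, "panel.csv")
        write_pipeline_csv(simulate_mechanism_panel(spec), p); note(p)
      }),
      mechanism = run_stage(stage, function(note) {
        panel <- read_pipeline_csv(need(stage, file.path(out, "panel.csv")))
        p <- file.path(out, "mechanism.csv")
        write_pipeline_csv(fit_mechanism_panel(panel), p); note(p)
      }),
      correlate = run_stage(stage, function(note) {
        mech <- read_pipeline_csv(need(stage, file.path(out, "mechanism.csv")))
        panel <- read_pipeline_csv(need(stage, file.path(out, "panel.csv")))
        phospho <- panel |>
          dplyr::group_by(.data$compound) |>
          dplyr::summarise(vesicles_per_cell = mean(.data$vesicles_per_cell),
                           .groups = "drop")
        pka_path <- file.path(out, "pka_fits.csv")
        pka <- if (file.exists(pka_path)) read_pipeline_csv(pka_path) else
          dplyr::select(config$compounds, "compound", "pka")
        summary <- build_compound_summary(mech, pka, phospho)
        p1 <- file.path(out, "compound_summary.csv")
        write_pipeline_csv(summary, p1); note(p1)
        cors <- dplyr::bind_rows(
          correlate_mechanism(summary, "efficiency"),
          correlate_mechanism(summary, "intercept")
        )
        p2 <- file.path(out, "correlations.csv")
        write_pipeline_csv(cors, p2); note(p2)
        p3 <- file.path(out, "correlations.json")
        jsonlite::write_json(cors, p3, auto_unbox = FALSE, digits = NA)
        note(p3)
      })
    )
  }

  written <- sort(unique(written))
  prefix <- paste0(sub("/+$", "", out), "/")
  manifest <- tibble::tibble(
    file = ifelse(startsWith(written, prefix),
                  substring(written, nchar(prefix) + 1), written),
    md5 = unname(tools::md5sum(written))
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = FALSE, digits = NA)
  say("wrote %d artifacts to %s", nrow(manifest), out)
  invisible(manifest)
}
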