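#' Read and validate a delimited table against a schema
#'
#' Tab-separated text with a header row is the canonical tabular format of
#' the package. The schema names the required columns and their types;
#' extra columns are preserved. Validation failures name the offending
#' column (and row where applicable).
#'
#' @param path File path.
#' @param schema Named character vector mapping required column names to
#'   types (`"integer"`, `"numeric"`, `"character"`).
#' @param sep Field separator (default tab).
#' @return The validated data frame.
#' @export
load_table <- function(path, schema, sep = "\t") {
  if (!file.exists(path)) stop("load_table(): no such file: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(names(schema), names(df))
  if (length(missing) > 0) {
    stop("load_table(): missing column(s): ", paste(missing, collapse = ", "))
  }
  for (col in names(schema)) {
    val <- df[[col]]
    ok <- switch(schema[[col]],
                 integer = is.numeric(val) && all(val == round(val), na.rm = TRUE),
                 numeric = is.numeric(val),
                 character = is.character(val) || is.factor(val),
                 stop("load_table(): unknown schema type ", schema[[col]]))
    if (!ok) stop("load_table(): column '", col, "' is not of type ",
                  schema[[col]])
    if (schema[[col]] == "integer") df[[col]] <- as.integer(val)
  }
  df
}

#' Read a variant read-count table
#'
#' Loads the deconvolution input contract: a tab-separated table with
#' columns `variant_id`, `sample_id`, `variant_reads`, `depth`. Rejects
#' negative counts and any row with more variant reads than depth.
#'
#' @param path File path.
#' @return Validated data frame.
#' @export
load_read_counts <- function(path) {
  df <- load_table(path, c(variant_id = "character", sample_id = "character",
                           variant_reads = "integer", depth = "integer"))
  bad <- which(df$variant_reads < 0 | df$depth <= 0 |
                 df$variant_reads > df$depth)
  if (length(bad) > 0) {
    stop("load_read_counts(): row ", bad[1],
         ": variant_reads must satisfy 0 <= r <= depth")
  }
  df
}

#' Write a variant read-count table
#'
#' @param counts Data frame with the read-count columns.
#' @param path Output path.
#' @export
write_read_counts <- function(counts, path) {
  utils::write.table(counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a regression dataset (response + design)
#'
#' The response file has one column `y`; the design file has one header
#' column per covariate. With `genotype = TRUE` the design entries must be
#' in the SNP dosage coding \{0, 1, 2\} (0 = homozygous reference AA,
#' 1 = heterozygous AB, 2 = homozygous alternate BB).
#'
#' @param response_path,design_path File paths (tab-separated, header row).
#' @param genotype Enforce \{0, 1, 2\} coding on the design?
#' @return List with `y` (numeric vector) and `Z` (numeric matrix).
#' @export
load_regression_data <- function(response_path, design_path,
                                 genotype = FALSE) {
  y <- load_table(response_path, c(y = "numeric"))$y
  Z <- as.matrix(utils::read.table(design_path, header = TRUE, sep = "\t",
                                   check.names = FALSE))
  if (!is.numeric(Z)) stop("load_regression_data(): design is not numeric")
  if (length(y) != nrow(Z)) {
    stop("load_regression_data(): response length ", length(y),
         " does not match design rows ", nrow(Z))
  }
  if (genotype && !all(Z %in% c(0, 1, 2))) {
    bad <- which(!(Z %in% c(0, 1, 2)))[1]
    stop("load_regression_data(): genotype value outside {0,1,2} at entry ",
         bad)
  }
  list(y = y, Z = Z)
}

#' Run a configured experiment end to end
#'
#' Dispatches one of the bundled experiments -- `"simulate"` (write a
#' synthetic dataset), `"toy"` (the mode-switching illustration),
#' `"regress"` (g-prior variable selection) or `"deconv"` (tumor
#' deconvolution) -- writes traces, summaries and a provenance manifest
#' (config, seed, package version) into the output directory.
#'
#' @param config Named list or path to a YAML file with keys: `experiment`,
#'   `out_dir`, `seed`, and experiment-specific settings (`recipe`,
#'   `input`, `kernel` settings `m`, `K`, `iterations`, `burn_in`, model
#'   hyperparameters as a `hyper` list).
#' @return Invisibly, the list of files written.
#' @export
run_experiment <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$experiment),
            !is.null(config$out_dir))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  written <- character(0)
  wr <- function(obj, name) {
    p <- file.path(out, name)
    utils::write.table(obj, p, sep = "\t", quote = FALSE, row.names = FALSE)
    written <<- c(written, p)
    p
  }
  switch(config$experiment,
    simulate = {
      recipe <- config$recipe %||% "tumor"
      if (recipe == "tumor") {
        sim <- gen_tumor(seed = seed, fresh = isTRUE(config$fresh))
        wr(sim$counts, "counts.tsv")
      } else if (recipe == "regression") {
        sim <- gen_regression(seed = seed,
                              N = config$N %||% 100,
                              D_half = config$D_half %||% 600)
        wr(data.frame(y = sim$y), "response.tsv")
        Z <- as.data.frame(sim$Z)
        names(Z) <- paste0("z", seq_len(ncol(Z)))
        wr(Z, "design.tsv")
      } else if (recipe == "toy") {
        sim <- gen_toy(config$sigma2 %||% 0.5, seed = seed)
        wr(data.frame(y = sim$y), "response.tsv")
        Z <- as.data.frame(sim$Z)
        names(Z) <- paste0("z", seq_len(ncol(Z)))
        wr(Z, "design.tsv")
      } else if (recipe == "multisample_tumor") {
        sim <- gen_multisample_tumor(S = config$S %||% 13, seed = seed)
        wr(sim$counts, "counts.tsv")
      } else stop("run_experiment(): unknown recipe '", recipe, "'")
    },
    toy = {
      res <- run_toy_experiment(
        sigma2 = config$sigma2 %||% c(0.5, 2, 5),
        iterations = config$iterations %||% 1000,
        burn_in = config$burn_in %||% 100, seed = seed)
      for (nm in names(res)) {
        wr(res[[nm]]$hb$x, paste0(nm, "_hb_states.tsv"))
        wr(res[[nm]]$gibbs$x, paste0(nm, "_gibbs_states.tsv"))
      }
      wr(data.frame(sigma2 = vapply(res, `[[`, 0, "sigma2"),
                    switches_hb = vapply(res, `[[`, 0L, "switches_hb"),
                    switches_gibbs = vapply(res, `[[`, 0L, "switches_gibbs")),
         "mode_switches.tsv")
    },
    regress = {
      data <- if (!is.null(config$input)) {
        load_regression_data(config$input$response, config$input$design,
                             genotype = isTRUE(config$input$genotype))
      } else {
        gen_regression(seed = seed)
      }
      chain <- regression_block_hb(
        data, K = config$K %||% 10, m = config$m %||% 1,
        iterations = config$iterations %||% 100000,
        burn_in = config$burn_in %||% 100, seed = seed,
        thin = config$thin %||% 1)
      wr(data.frame(covariate = seq_len(chain$D),
                    inclusion = chain$inclusion), "inclusion.tsv")
      wr(data.frame(iteration = seq_along(chain$logml),
                    logml = chain$logml), "logml_trace.tsv")
      supp <- vapply(chain$support, paste, "", collapse = ",")
      wr(data.frame(iteration = seq_along(supp), support = supp),
         "support_trace.tsv")
    },
    deconv = {
      counts <- if (!is.null(config$input)) {
        load_read_counts(config$input)
      } else {
        gen_tumor()$counts
      }
      hl <- config$hyper %||% list()
      if (is.null(hl$m) && !is.null(config$m)) hl$m <- config$m
      if (is.null(hl$K) && !is.null(config$K)) hl$K <- config$K
      hy <- do.call(deconv_hyper, hl)
      fit <- deconv_hb(counts, hyper = hy,
                       iterations = config$iterations %||% 20000,
                       burn_in = config$burn_in %||% 10000, seed = seed,
                       thin = config$thin %||% 1)
      wr(cbind(iteration = seq_len(nrow(fit$max_theta)),
               as.data.frame(fit$max_theta)), "max_theta_trace.tsv")
      wr(as.data.frame(fit$phi_mean), "phi_mean.tsv")
      wr(as.data.frame(residual_matrix(fit$r, fit$d, fit$phi_mean)),
         "residuals.tsv")
      wr(data.frame(accept_rate = fit$accept_rate,
                    sigma_v2 = fit$sigma_v2), "acceptance.tsv")
    },
    stop("run_experiment(): unknown experiment '", config$experiment, "'")
  )
  manifest <- list(experiment = config$experiment, seed = seed,
                   config = config,
                   package_version = as.character(
                     utils::packageVersion("hamball")),
                   r_version = R.version.string,
                   files = basename(written))
  mpath <- file.path(out, "manifest.yaml")
  yaml::write_yaml(manifest, mpath)
  invisible(c(written, mpath))
}
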