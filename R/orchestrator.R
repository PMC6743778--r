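# Configuration-driven end-to-end benchmark runs.

#' Default benchmark configuration
#'
#' Returns the default configuration list; user-supplied values override
#' these. Networks, label streams and the complex catalog may be given as
#' file paths (TSV, see the respective readers) or as in-memory objects.
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(
    networks = list(),          # named: path or igraph
    labels = NULL,              # path or data.frame (gene, disease, stream, score)
    complexes = list(),         # path or named list of gene sets
    diseases = NULL,            # allow-list; NULL = all in the label table
    methods = c("raw", "z", "pr", "random"),
    cv = list(schemes = c("classic", "block", "representative"),
              k = 3L, repeats = 25L, seed = 1L),
    metrics = c("auroc", "top20"),
    inputs = c("drugs"),        # streams used to seed the methods
    genetic_threshold = 0.16,
    min_positives = 50L,
    damping = 0.85,
    n_perm = 1000L,
    out_dir = NULL
  )
}

#' Merge a user configuration over the defaults
#' @noRd
resolve_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- default_config()
  for (nm in names(config)) {
    if (nm == "cv" && is.list(config$cv)) {
      for (cn in names(config$cv)) cfg$cv[[cn]] <- config$cv[[cn]]
    } else {
      cfg[[nm]] <- config[[nm]]
    }
  }
  if (cfg$cv$k < 2L) stop("cv k must be at least 2", call. = FALSE)
  if (cfg$cv$repeats < 1L) stop("cv repeats must be at least 1", call. = FALSE)
  bad <- setdiff(cfg$methods, available_methods())
  if (length(bad) > 0L) {
    stop("unknown method(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  cfg
}

#' Run the full benchmark described by a configuration
#'
#' For every network x disease x CV scheme x input stream x method cell:
#' folds are always built on the drugs-stream positives, the repeated CV of
#' [repeated_cv()] is run with the configured input stream seeding the
#' method, and metric records are accumulated. Explanatory models
#' ([fit_additive_model()]) are then fitted per (metric, input stream). All
#' randomness derives from the single configured seed. A failing method
#' cell is logged and skipped; unreadable inputs abort before any
#' computation.
#'
#' If `out_dir` is set, `records.csv`, `model_coefficients.csv` and
#' `manifest.json` are written there.
#'
#' @param config Configuration list or path to a YAML file; see
#'   [default_config()] for the recognised fields.
#' @return List with `records` (metric-record data frame), `models` (named
#'   list of `perf_model`), and `skipped` (character log of skipped cells).
#' @export
run_benchmark <- function(config) {
  cfg <- resolve_config(config)

  # --- load all inputs up front so bad paths abort before computing
  networks <- lapply(cfg$networks, function(nw) {
    g <- if (is.character(nw)) read_edge_list(nw) else nw
    stopifnot(inherits(g, "igraph"))
    largest_connected_component(g)
  })
  if (length(networks) == 0L) stop("no networks configured", call. = FALSE)
  label_table <- cfg$labels
  if (is.character(label_table)) {
    label_table <- utils::read.delim(label_table, stringsAsFactors = FALSE)
  }
  labels <- if (is.data.frame(label_table)) {
    binarise_inputs(label_table, cfg$genetic_threshold)
  } else if (is.list(label_table)) {
    label_table
  } else {
    stop("no label streams configured", call. = FALSE)
  }
  catalog <- if (is.character(cfg$complexes)) {
    read_complex_catalog(cfg$complexes)
  } else {
    cfg$complexes
  }
  diseases <- cfg$diseases %||%
    unique(vapply(labels, function(l) l$disease, ""))

  kernel_methods <- c("raw", "gm", "mc", "z", "knn", "wsld", "bagsvm",
                      "randomraw")
  feature_methods <- c("rf", "svm")
  opts <- list(damping = cfg$damping, n_perm = cfg$n_perm)

  records <- list()
  skipped <- character(0)
  cell <- 0L
  for (nw in names(networks)) {
    g <- networks[[nw]]
    K <- if (any(cfg$methods %in% kernel_methods)) {
      regularized_laplacian_kernel(g)
    } else NULL
    features <- if (any(cfg$methods %in% feature_methods)) {
      diffusion_state_features(g)
    } else NULL
    for (dz in diseases) {
      drugs <- labels[[paste(dz, "drugs", sep = ".")]]
      if (is.null(drugs)) {
        skipped <- c(skipped, sprintf("%s/%s: no drugs stream", nw, dz))
        next
      }
      n_pos <- length(intersect(drugs$positives, node_index(g)))
      if (n_pos < cfg$min_positives) {
        skipped <- c(skipped,
                     sprintf("%s/%s: %d positives below the minimum of %d",
                             nw, dz, n_pos, cfg$min_positives))
        next
      }
      for (input in cfg$inputs) {
        input_labels <- labels[[paste(dz, input, sep = ".")]]
        if (is.null(input_labels)) {
          skipped <- c(skipped, sprintf("%s/%s: no %s stream", nw, dz, input))
          next
        }
        for (scheme in cfg$cv$schemes) {
          for (method in cfg$methods) {
            cell <- cell + 1L
            cell_seed <- cfg$cv$seed + 101L * cell
            rec <- tryCatch(
              repeated_cv(method, g = g, K = K,
                          input_labels = input_labels, eval_labels = drugs,
                          scheme = scheme, catalog = catalog,
                          k = cfg$cv$k, repeats = cfg$cv$repeats,
                          metrics = cfg$metrics, seed = cell_seed,
                          network = nw, features = features, opts = opts),
              error = function(e) {
                skipped <<- c(skipped, sprintf("%s/%s/%s/%s/%s: %s",
                                               nw, dz, input, scheme, method,
                                               conditionMessage(e)))
                NULL
              })
            if (!is.null(rec)) {
              rec$input <- input
              records[[length(records) + 1L]] <- rec
            }
          }
        }
      }
    }
  }
  records <- if (length(records) > 0L) do.call(rbind, records) else
    stop("no benchmark cells produced records", call. = FALSE)

  models <- list()
  for (input in unique(records$input)) {
    for (metric in cfg$metrics) {
      sub <- records[records$input == input, , drop = FALSE]
      key <- paste(metric, input, sep = ".")
      models[[key]] <- tryCatch(
        suppressWarnings(fit_additive_model(sub, metric, "main")),
        error = function(e) {
          skipped <<- c(skipped, sprintf("model %s: %s", key,
                                         conditionMessage(e)))
          NULL
        })
    }
  }

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(records, file.path(cfg$out_dir, "records.csv"),
                     row.names = FALSE)
    coefs <- do.call(rbind, lapply(names(models), function(key) {
      if (is.null(models[[key]])) return(NULL)
      cbind(model = key, models[[key]]$coefficients)
    }))
    if (!is.null(coefs)) {
      utils::write.csv(coefs, file.path(cfg$out_dir, "model_coefficients.csv"),
                       row.names = FALSE)
    }
    manifest <- list(
      package_version = as.character(utils::packageVersion("netbench")),
      r_version = R.version.string,
      config_hash = config_hash(cfg),
      n_records = nrow(records),
      skipped = skipped
    )
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(records = records, models = models, skipped = skipped)
}

#' md5 of the serialised (deparsed) configuration
#' @noRd
config_hash <- function(cfg) {
  tf <- tempfile()
  on.exit(unlink(tf))
  # igraph objects carry environments; hash a stable textual summary instead
  stable <- lapply(cfg, function(x) {
    if (inherits(x, "igraph")) sprintf("igraph<%d,%d>", igraph::vcount(x),
                                       igraph::ecount(x)) else x
  })
  writeLines(utils::capture.output(utils::str(stable)), tf)
  unname(tools::md5sum(tf))
}
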