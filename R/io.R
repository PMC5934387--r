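# Readers and writers: TSV/CSV matrices (first column = feature ID, header =
# sample IDs), two-column label and probe-map files, plain key=value config
# files, and JSON model serialization with a byte-exact round trip.

#' @noRd
.sep_for <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

#' Read an expression matrix from TSV/CSV
#'
#' First column = feature IDs, header = sample IDs. Duplicate IDs and
#' non-numeric cells raise descriptive errors.
#'
#' @param path file path; `.csv` files are comma-separated, anything else
#'   tab-separated.
#' @return numeric matrix, features x samples.
#' @export
read_expression <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = .sep_for(path),
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "", comment.char = "")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate feature ID(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  samples <- names(df)[-1]
  if (anyDuplicated(samples))
    stop("duplicate sample ID(s): ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(vals[[j]]))))[1]
      stop("non-numeric value in column '", names(vals)[j], "', data row ",
           bad, " (file line ", bad + 1, ")")
    }
  }
  x <- as.matrix(vals)
  rownames(x) <- ids
  colnames(x) <- samples
  x
}

#' Write a matrix as TSV/CSV with a feature-ID first column
#' @param x matrix with dimnames.
#' @param path destination; extension selects the separator.
#' @param id_name header of the first column.
#' @export
write_matrix <- function(x, path, id_name = "feature_id") {
  df <- data.frame(rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_name
  utils::write.table(df, path, sep = .sep_for(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read per-sample binary class labels
#'
#' Two-column file (sample_id, class in \{0, 1\}), with or without a header.
#'
#' @param path file path.
#' @return named integer vector of 0/1 labels.
#' @export
read_labels <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = .sep_for(path),
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  if (!is.numeric(df[[2]]) && suppressWarnings(is.na(as.numeric(df[1, 2]))))
    df <- df[-1, , drop = FALSE]  # header row
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate sample ID(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  labels <- as.integer(df[[2]])
  if (any(is.na(labels)) || !all(labels %in% c(0L, 1L)))
    stop("labels must be 0/1")
  stats::setNames(labels, ids)
}

#' Read a probe-to-gene mapping table
#'
#' Two-column file (probe_id, gene_id); a probe may appear on several lines
#' (multi-mapped).
#'
#' @param path file path.
#' @return data.frame with `probe_id`, `gene_id`.
#' @export
read_probe_map <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = .sep_for(path),
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  if (nrow(df) > 0 && identical(tolower(as.character(df[1, 1])), "probe_id"))
    df <- df[-1, , drop = FALSE]
  unique(data.frame(probe_id = as.character(df[[1]]),
                    gene_id = as.character(df[[2]]),
                    stringsAsFactors = FALSE))
}

#' Read a plain key = value configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment. Values that parse
#' as numbers are returned numeric.
#'
#' @param path file path.
#' @return named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

# --- model serialization --------------------------------------------------

#' @noRd
.ensemble_to_list <- function(ens) {
  list(
    format = "modulebayes_ensemble",
    version = 1L,
    k = ens$k,
    seed = ens$seed,
    nodes = ens$nodes,
    config = unclass(ens$config),
    eigen_model = if (!is.null(ens$eigen_model)) list(
      modules = lapply(ens$eigen_model$modules, function(m)
        list(genes = m$genes, weights = unname(m$weights))),
      center = as.list(ens$eigen_model$center),
      scale = as.list(ens$eigen_model$scale),
      factors = as.list(ens$eigen_model$factors)
    ),
    discretization = list(
      levels = ens$discretization$levels,
      ibreaks = ens$discretization$ibreaks,
      vars = ens$discretization$vars,
      cuts = lapply(ens$discretization$cuts, function(cc) as.list(cc))
    ),
    models = lapply(ens$models, function(m) {
      arcs <- dag_arcs(m$dag)
      list(
        nodes = colnames(m$dag),
        arcs = if (nrow(arcs)) lapply(seq_len(nrow(arcs)), function(i)
          as.list(unname(arcs[i, ]))) else list(),
        iss = m$iss,
        levels = as.list(m$levels),
        level_labels = m$level_labels,
        cpts = lapply(m$cpts, function(cpt) list(
          dim = dim(cpt),
          parents = names(dimnames(cpt))[-1],
          values = as.vector(cpt)
        ))
      )
    })
  )
}

#' @noRd
.ensemble_from_list <- function(obj) {
  stopifnot(identical(obj$format, "modulebayes_ensemble"))
  nodes <- unlist(obj$nodes)
  cfg_in <- obj$config
  config <- bn_config(R = cfg_in$R, top_fraction = cfg_in$top_fraction,
                      strength_threshold = cfg_in$strength_threshold,
                      iss = cfg_in$iss, levels = cfg_in$levels,
                      ibreaks = cfg_in$ibreaks, restarts = cfg_in$restarts,
                      tol = cfg_in$tol, n_particles = cfg_in$n_particles)
  eigen_model <- NULL
  if (!is.null(obj$eigen_model)) {
    em <- obj$eigen_model
    eigen_model <- structure(list(
      modules = lapply(em$modules, function(m) {
        genes <- unlist(m$genes)
        list(genes = genes,
             weights = stats::setNames(unlist(m$weights), genes))
      }),
      center = unlist(em$center),
      scale = unlist(em$scale),
      factors = stats::setNames(as.integer(unlist(em$factors)),
                                names(em$factors))
    ), class = "eigengene_model")
  }
  dm <- obj$discretization
  disc <- structure(list(
    cuts = stats::setNames(lapply(dm$vars, function(v) {
      cc <- dm$cuts[[v]]
      if (is.null(cc) || length(cc) == 0) NULL else as.numeric(unlist(cc))
    }), unlist(dm$vars)),
    levels = as.integer(dm$levels),
    ibreaks = as.integer(dm$ibreaks),
    vars = unlist(dm$vars)
  ), class = "discretization_model")
  models <- lapply(obj$models, function(mo) {
    mnodes <- unlist(mo$nodes)
    dag <- empty_dag(mnodes)
    for (arc in mo$arcs) dag[arc[[1]], arc[[2]]] <- TRUE
    levels <- stats::setNames(as.integer(unlist(mo$levels)),
                              names(mo$levels))
    level_labels <- lapply(mo$level_labels, function(v) unlist(v))
    cpts <- stats::setNames(lapply(mnodes, function(v) {
      cp <- mo$cpts[[v]]
      parents <- unlist(cp$parents)
      cpt <- array(as.numeric(unlist(cp$values)),
                   dim = as.integer(unlist(cp$dim)),
                   dimnames = c(list(level_labels[[v]]),
                                level_labels[parents]))
      names(dimnames(cpt)) <- c(v, parents)
      cpt
    }), mnodes)
    structure(list(dag = dag, cpts = cpts, levels = levels,
                   level_labels = level_labels, iss = mo$iss),
              class = "bn_model")
  })
  structure(list(eigen_model = eigen_model, discretization = disc,
                 discrete = NULL, models = models, strengths = NULL,
                 folds = NULL, labels = NULL, k = obj$k, seed = obj$seed,
                 config = config, nodes = nodes),
            class = "ensemble_model")
}

#' Save an ensemble model as JSON
#'
#' Full-precision serialization: `save_model(load_model(f), g)` writes a
#' byte-identical file and the reloaded model makes identical predictions.
#'
#' @param model an `ensemble_model` (or `modulebayes_classifier`).
#' @param path destination `.json` path.
#' @export
save_model <- function(model, path) {
  if (inherits(model, "modulebayes_classifier")) model <- model$ensemble
  stopifnot(inherits(model, "ensemble_model"))
  jsonlite::write_json(.ensemble_to_list(model), path, digits = I(17),
                       auto_unbox = TRUE, null = "null", pretty = TRUE)
  invisible(path)
}

#' Load an ensemble model saved by [save_model()]
#' @param path `.json` path.
#' @return an `ensemble_model`.
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  .ensemble_from_list(obj)
}
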