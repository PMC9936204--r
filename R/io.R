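#' Construct a validated count matrix container
#'
#' The pipeline's single entry object: an integer probe-by-sample count
#' matrix together with its probe annotation and sample metadata tables.
#'
#' @param counts integer matrix, probes in rows, samples in columns.
#' @param probes data.frame with columns `probe_id`, `gene_symbol`,
#'   `entrez_id` (integer, may be NA) and `maps_multiple_genes` (logical).
#' @param samples data.frame with columns `sample_id`, `plate`, `chemical`,
#'   `concentration_uM`, `replicate` and `role` (one of `treated`,
#'   `solvent_control`, `reference`, `no_cell`).
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, probes, samples) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"   # integer-valued; double avoids overflow
  probes <- as.data.frame(probes)
  samples <- as.data.frame(samples)

  need_p <- c("probe_id", "gene_symbol", "entrez_id", "maps_multiple_genes")
  need_s <- c("sample_id", "plate", "chemical", "concentration_uM",
              "replicate", "role")
  miss <- setdiff(need_p, names(probes))
  if (length(miss)) stop("probe annotation missing column(s): ",
                         paste(miss, collapse = ", "))
  miss <- setdiff(need_s, names(samples))
  if (length(miss)) stop("sample metadata missing column(s): ",
                         paste(miss, collapse = ", "))

  if (nrow(counts) != nrow(probes)) {
    stop("count matrix has ", nrow(counts), " rows but annotation lists ",
         nrow(probes), " probes")
  }
  if (ncol(counts) != nrow(samples)) {
    stop("count matrix has ", ncol(counts), " columns but metadata lists ",
         nrow(samples), " samples")
  }
  if (anyDuplicated(probes$probe_id)) {
    stop("duplicate probe_id: ",
         probes$probe_id[duplicated(probes$probe_id)][1])
  }
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicate sample_id: ",
         samples$sample_id[duplicated(samples$sample_id)][1])
  }
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts))
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(counts))
    stop("counts must be non-negative integers; offending entry at probe '",
         probes$probe_id[rc[1]], "', sample '", samples$sample_id[rc[2]], "'")
  }
  roles <- c("treated", "solvent_control", "reference", "no_cell")
  bad <- which(!samples$role %in% roles)
  if (length(bad)) {
    stop("unknown role '", samples$role[bad[1]], "' in metadata row for sample '",
         samples$sample_id[bad[1]], "'")
  }
  if (any(samples$concentration_uM < 0)) {
    bad <- which(samples$concentration_uM < 0)[1]
    stop("negative concentration for sample '", samples$sample_id[bad], "'")
  }
  bad <- which(samples$role == "solvent_control" & samples$concentration_uM != 0)
  if (length(bad)) {
    stop("solvent_control sample '", samples$sample_id[bad[1]],
         "' has non-zero concentration")
  }
  # every treated (chemical, plate) must have a plate-matched solvent control
  tr <- samples[samples$role == "treated", , drop = FALSE]
  ctl_plates <- unique(samples$plate[samples$role == "solvent_control"])
  bad <- unique(tr$plate[!tr$plate %in% ctl_plates])
  if (length(bad)) {
    stop("treated samples on plate '", bad[1],
         "' have no plate-matched solvent control")
  }
  dimnames(counts) <- list(probes$probe_id, samples$sample_id)
  structure(list(counts = counts, probes = probes, samples = samples),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix: ", nrow(x$counts), " probes x ", ncol(x$counts),
      " samples\n", sep = "")
  cat("  chemicals:", paste(unique(x$samples$chemical[
    x$samples$role == "treated"]), collapse = ", "), "\n")
  invisible(x)
}

#' Read counts, probe annotation and sample metadata from disk
#'
#' @param path counts file: either a TSV with probe ids in the first column
#'   and sample ids as header, or a MatrixMarket `.mtx` file whose rows
#'   follow the annotation file order and columns the metadata order.
#' @param annotation_path TSV of probe annotations (see [count_matrix()]).
#' @param metadata_path TSV of sample metadata.
#' @return A validated [count_matrix()].
#' @export
read_counts <- function(path, annotation_path, metadata_path) {
  for (f in c(path, annotation_path, metadata_path)) {
    if (!file.exists(f)) stop("file not found: ", f)
  }
  probes <- utils::read.delim(annotation_path, stringsAsFactors = FALSE)
  samples <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  if ("maps_multiple_genes" %in% names(probes)) {
    probes$maps_multiple_genes <- as.logical(probes$maps_multiple_genes)
  }
  if (grepl("\\.mtx$", path)) {
    m <- as.matrix(Matrix::readMM(path))
    counts <- m
  } else {
    tab <- utils::read.delim(path, check.names = FALSE,
                             stringsAsFactors = FALSE)
    counts <- as.matrix(tab[, -1, drop = FALSE])
    rownames(counts) <- tab[[1]]
    if (!is.null(probes$probe_id) &&
        all(probes$probe_id %in% rownames(counts)) &&
        nrow(counts) == nrow(probes)) {
      counts <- counts[probes$probe_id, , drop = FALSE]
    }
    if (all(samples$sample_id %in% colnames(counts)) &&
        ncol(counts) == nrow(samples)) {
      counts <- counts[, samples$sample_id, drop = FALSE]
    }
  }
  count_matrix(counts, probes, samples)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, `set_id <TAB> description <TAB> members...`.
#' The coverage denominator (total annotated genes in the set, which may
#' exceed the measured members listed in the GMT) can be supplied through a
#' companion table; it defaults to the member count.
#'
#' @param path GMT file path.
#' @param total_sizes optional: either a named numeric vector
#'   (set_id -> total annotated size) or the path of a two-column TSV.
#' @param source_label collection label, e.g. "GO", "Reactome", "KEGG".
#' @return A `gene_set_collection`: list with `source_label` and `sets`, a
#'   named list of `list(name, members, total)`.
#' @export
read_gmt <- function(path, total_sizes = NULL, source_label = "other") {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (is.character(total_sizes) && length(total_sizes) == 1 &&
      file.exists(total_sizes)) {
    tab <- utils::read.delim(total_sizes, stringsAsFactors = FALSE)
    total_sizes <- stats::setNames(as.numeric(tab[[2]]), tab[[1]])
  }
  sets <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 2) stop("malformed GMT line: ", substr(ln, 1, 40))
    id <- f[1]
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members)) {
      warning("gene set '", id, "' has no members; skipped")
      next
    }
    if (id %in% names(sets)) stop("duplicate gene-set id: ", id)
    total <- length(members)
    if (!is.null(total_sizes) && id %in% names(total_sizes)) {
      total <- max(total_sizes[[id]], length(members))
    }
    sets[[id]] <- list(name = f[2], members = members, total = total)
  }
  structure(list(source_label = source_label, sets = sets),
            class = "gene_set_collection")
}

#' Read a directional biomarker signature
#'
#' Two-column table: gene identifier and expected direction under pathway
#' activation (`+1`/`-1`, or `up`/`down`).
#'
#' @param path TSV path (header required).
#' @param name signature name; defaults to the file stem.
#' @param call_threshold score magnitude for a categorical call (default 4,
#'   i.e. a Bonferroni-corrected running-Fisher p of 1e-4).
#' @return A `biomarker_signature`: list with `name`, `entries` (data.frame
#'   `gene`, `direction`) and `call_threshold`.
#' @export
read_biomarker <- function(path, name = NULL, call_threshold = 4) {
  if (!file.exists(path)) stop("signature file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0) stop("signature file is empty: ", path)
  if (ncol(tab) < 2) stop("signature must have two columns (gene, direction)")
  gene <- as.character(tab[[1]])
  dir_raw <- tolower(as.character(tab[[2]]))
  direction <- ifelse(dir_raw %in% c("1", "+1", "up"), 1,
               ifelse(dir_raw %in% c("-1", "down"), -1, NA))
  if (anyNA(direction)) {
    stop("invalid direction '", tab[[2]][which(is.na(direction))[1]],
         "' (use +1/-1 or up/down)")
  }
  if (anyDuplicated(gene)) {
    stop("duplicate gene in signature: ", gene[duplicated(gene)][1])
  }
  biomarker_signature(name %||% sub("\\.[^.]*$", "", basename(path)),
                      gene, direction, call_threshold)
}

#' @rdname read_biomarker
#' @param gene,direction vectors defining the signature programmatically.
#' @export
biomarker_signature <- function(name, gene, direction, call_threshold = 4) {
  stopifnot(length(gene) == length(direction),
            all(direction %in% c(-1, 1)), call_threshold > 0)
  if (anyDuplicated(gene)) stop("duplicate gene in signature")
  structure(list(name = name,
                 entries = data.frame(gene = as.character(gene),
                                      direction = as.integer(direction),
                                      stringsAsFactors = FALSE),
                 call_threshold = call_threshold),
            class = "biomarker_signature")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write pipeline result tables
#'
#' One TSV per stage, deterministic column order, reals at full precision
#' (15 significant digits) so a read-back reproduces values.
#'
#' @param tables named list of data.frames (e.g. `qc_report`, `biosets`,
#'   `biomarker_calls`, `gene_bmcs`, `tpods`, `ranking`).
#' @param out_dir output directory, created if needed.
#' @return Named character vector of written paths, invisibly.
#' @export
write_results <- function(tables, out_dir) {
  stopifnot(is.list(tables), !is.null(names(tables)))
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE,
                                          showWarnings = FALSE)
  if (!ok || file.access(out_dir, 2) != 0) {
    stop("cannot write to directory: ", out_dir)
  }
  paths <- character(0)
  for (nm in names(tables)) {
    tab <- as.data.frame(tables[[nm]])
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    num <- vapply(tab, is.double, logical(1))
    tab[num] <- lapply(tab[num], function(x) {
      ifelse(is.na(x), NA, formatC(x, digits = 15, format = "g"))
    })
    utils::write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "NA")
    paths[nm] <- p
  }
  invisible(paths)
}

#' Read back a result table written by [write_results()]
#' @param path TSV path.
#' @return data.frame.
#' @export
read_result <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
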