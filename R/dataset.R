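# Dataset container: a collection of connectomes plus the species table
# (species -> taxonomic order / superorder, and the samples per species).

#' Construct a dataset
#'
#' @param connectomes list of [connectome] objects (one per scan).
#' @param species data.frame with columns `species_id`, `order`,
#'   `superorder`; one row per species. Every connectome's `species_id`
#'   must appear exactly once here and every species must carry an order
#'   label.
#' @param parcellation_size expected node count shared by all connectomes
#'   (default taken from the first connectome).
#' @return an object of class `connectome_dataset` with elements
#'   `connectomes` (named by sample_id), `species`, `parcellation_size`.
#' @export
connectome_dataset <- function(connectomes, species,
                               parcellation_size = NULL) {
  stopifnot(length(connectomes) >= 1)
  sample_ids <- vapply(connectomes, `[[`, "", "sample_id")
  if (anyDuplicated(sample_ids)) stop("dataset: duplicate sample_id")
  names(connectomes) <- sample_ids
  ns <- vapply(connectomes, `[[`, 0, "n_nodes")
  if (is.null(parcellation_size)) parcellation_size <- ns[[1]]
  if (!all(ns == parcellation_size)) {
    stop("dataset: inconsistent node counts across samples")
  }
  species <- as.data.frame(species, stringsAsFactors = FALSE)
  req <- c("species_id", "order", "superorder")
  if (!all(req %in% names(species))) {
    stop("dataset: species table needs columns ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(species$species_id)) {
    stop("dataset: duplicate species_id in species table")
  }
  if (any(is.na(species$order) | species$order == "")) {
    stop("dataset: every species must have an order label")
  }
  sp_of_sample <- vapply(connectomes, `[[`, "", "species_id")
  if (!all(sp_of_sample %in% species$species_id)) {
    stop("dataset: connectome species_id missing from species table")
  }
  structure(
    list(connectomes = connectomes, species = species,
         parcellation_size = as.integer(parcellation_size)),
    class = "connectome_dataset")
}

#' @export
print.connectome_dataset <- function(x, ...) {
  cat(sprintf(
    "<connectome_dataset> %d samples, %d species, %d orders, %d nodes\n",
    length(x$connectomes), nrow(x$species),
    length(unique(x$species$order)), x$parcellation_size))
  invisible(x)
}

#' Samples belonging to each species
#'
#' @param dataset a [connectome_dataset].
#' @return named list mapping species_id to the sample_ids of its scans.
#' @export
species_samples <- function(dataset) {
  sp <- vapply(dataset$connectomes, `[[`, "", "species_id")
  split(names(dataset$connectomes), factor(sp, levels = dataset$species$species_id))
}

#' Load a dataset from a manifest file
#'
#' The manifest is a TSV with header and columns `species_id`, `order`,
#' `superorder`, `sample_id`, `matrix_path`, `metadata_path`; one row per
#' scan. Relative paths are resolved against the manifest's directory.
#'
#' @param manifest_path path to the manifest TSV.
#' @return a [connectome_dataset].
#' @export
load_dataset <- function(manifest_path) {
  man <- read.table(manifest_path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
  req <- c("species_id", "order", "superorder", "sample_id",
           "matrix_path", "metadata_path")
  if (!all(req %in% names(man))) {
    stop("load_dataset: manifest needs columns ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(man$sample_id)) stop("load_dataset: duplicate sample_id")
  base <- dirname(manifest_path)
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p,
                                file.path(base, p))
  cons <- lapply(seq_len(nrow(man)), function(i) {
    read_connectome(resolve(man$matrix_path[i]), resolve(man$metadata_path[i]),
                    species_id = man$species_id[i],
                    sample_id = man$sample_id[i])
  })
  sp <- unique(man[, c("species_id", "order", "superorder")])
  if (anyDuplicated(sp$species_id)) {
    stop("load_dataset: species mapped to more than one order/superorder")
  }
  ds <- connectome_dataset(cons, sp)
  ctx_log(sprintf("loaded %d samples / %d species from %s",
                  length(cons), nrow(sp), manifest_path))
  ds
}

#' Write a dataset (manifest + per-sample files)
#'
#' @param dataset a [connectome_dataset].
#' @param out_dir output directory (created if absent).
#' @return the manifest path, invisibly.
#' @export
write_dataset <- function(dataset, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  man <- do.call(rbind, lapply(dataset$connectomes, function(con) {
    mp <- paste0(con$sample_id, "_weights.csv")
    np <- paste0(con$sample_id, "_nodes.tsv")
    write_connectome(con, file.path(out_dir, mp), file.path(out_dir, np))
    srow <- dataset$species[dataset$species$species_id == con$species_id, ]
    data.frame(species_id = con$species_id, order = srow$order,
               superorder = srow$superorder, sample_id = con$sample_id,
               matrix_path = mp, metadata_path = np)
  }))
  manifest_path <- file.path(out_dir, "manifest.tsv")
  write.table(man, manifest_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(manifest_path)
}

#' Keep only taxonomic orders with enough distinct species
#'
#' Mirrors the study design of restricting analyses to orders with at
#' least `min_species` distinct species. Idempotent and monotone in
#' `min_species`. Excluded orders are logged.
#'
#' @param dataset a [connectome_dataset].
#' @param min_species minimum number of distinct species per retained
#'   order (default 5).
#' @return the filtered [connectome_dataset].
#' @export
filter_orders <- function(dataset, min_species = 5) {
  stopifnot(min_species >= 1)
  counts <- table(dataset$species$order)
  keep_orders <- names(counts)[counts >= min_species]
  drop_orders <- setdiff(names(counts), keep_orders)
  for (o in drop_orders) {
    ctx_log(sprintf("filter_orders: excluding order %s (%d species < %d)",
                    o, counts[[o]], min_species))
  }
  sp <- dataset$species[dataset$species$order %in% keep_orders, , drop = FALSE]
  if (nrow(sp) == 0) stop("filter_orders: no orders retained")
  cons <- Filter(function(con) con$species_id %in% sp$species_id,
                 dataset$connectomes)
  ctx_log(sprintf("filter_orders: retained %d orders, %d species, %d samples",
                  length(keep_orders), nrow(sp), length(cons)))
  connectome_dataset(cons, sp, dataset$parcellation_size)
}
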