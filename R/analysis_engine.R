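#' Analysis options
#'
#' @param project map matched entities to their reference-species orthologs
#'   before aggregation (species projection)? Default `FALSE`.
#' @param reference_species projection target (and fallback species when a
#'   sample maps to nothing); defaults to `"Homo sapiens"`.
#' @return an `analysis_options` list. `include_interactors` is always
#'   `FALSE`: interactor augmentation is outside this engine.
#' @export
analysis_options <- function(project = FALSE, reference_species = "Homo sapiens") {
  stopifnot(is.logical(project), length(project) == 1L,
            is.character(reference_species), length(reference_species) == 1L)
  structure(
    list(project = project, reference_species = reference_species,
         include_interactors = FALSE),
    class = "analysis_options"
  )
}

#' Read a user sample from a plain-text identifier list
#'
#' One identifier per line; blank lines and lines starting with `#` are
#' ignored; only the first whitespace-separated column is used (extra
#' expression columns are tolerated and dropped).
#'
#' @param path file path.
#' @return character vector of submitted identifiers.
#' @export
read_sample <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  vapply(strsplit(lines, "[[:space:]]+"), `[[`, character(1), 1L)
}

#' Run an over-representation analysis
#'
#' Executes the four steps of the in-memory ORA pipeline:
#'
#' 1. every (deduplicated, normalised) identifier is looked up in the radix
#'    trie, partitioning the sample into mapped and not-found;
#' 2. matched single entities are — with projection enabled — replaced by
#'    their reference-species orthologs, then the entity graph is traversed
#'    to collect each entity's pathway links through all containing
#'    complexes/sets;
#' 3. each link marks a hit on the pathway hierarchy, propagated
#'    recursively to all super-pathways, in a per-analysis found-state;
#' 4. per-pathway binomial statistics and Benjamini-Hochberg FDR are
#'    computed over the filled state.
#'
#' Identifiers that resolve only to container entities (possible when a
#' knowledge base aliases a complex or set) are reported in the mapping but
#' excluded from the statistics, which count curated single entities.
#' Multi-species samples without projection are analysed per species, with
#' the FDR adjustment applied once across all reported rows.
#'
#' @param identifiers character vector of submitted identifiers.
#' @param kb a [load_knowledge_base()] result.
#' @param options an [analysis_options()] object.
#' @return an `analysis_result`: `rows` (the statistics table, sorted by
#'   ascending p-value), `mapping` (submitted identifier -> matched main
#'   identifiers), `not_found`, `unprojected` (mapped but lacking a
#'   reference-species ortholog; projection runs only), `options`, and
#'   `summary` (submitted / mapped sample sizes and background sizes).
#' @export
run_analysis <- function(identifiers, kb, options = analysis_options()) {
  stopifnot(inherits(kb, "knowledge_base"), inherits(options, "analysis_options"))
  g <- kb$graph
  f <- kb$forest
  ref <- options$reference_species
  if (options$project && !ref %in% g$species) {
    stop(sprintf("unknown reference species '%s'", ref), call. = FALSE)
  }

  submitted <- trimws(as.character(identifiers))
  submitted <- submitted[nzchar(submitted)]
  keys <- normalize_identifier(submitted, kb$case_insensitive)
  keep <- !duplicated(keys)
  submitted <- submitted[keep]
  keys <- keys[keep]
  if (!length(submitted)) {
    stop("run_analysis(): no identifiers submitted", call. = FALSE)
  }

  mapping <- list()
  not_found <- character(0)
  matches <- list()   # submitted -> matched single-entity ids
  for (i in seq_along(submitted)) {
    payload <- trie_lookup(kb$trie, keys[[i]])
    if (is.null(payload)) {
      not_found <- c(not_found, submitted[[i]])
      next
    }
    ids <- names(payload)
    singles <- ids[vapply(ids, function(id) is_single_entity(g$nodes[[id]]), logical(1))]
    containers <- setdiff(ids, singles)
    mapping[[submitted[[i]]]] <- sort_c(c(
      vapply(singles, function(id) g$nodes[[id]]$main_identifier, character(1)),
      containers
    ))
    matches[[submitted[[i]]]] <- singles
  }

  matched_ids <- sort_c(unlist(matches, use.names = FALSE))
  unprojected <- character(0)
  if (options$project && length(matched_ids)) {
    pr <- project_orthologs(g, matched_ids, ref)
    final_ids <- pr$projected
    for (s in names(matches)) {
      fin <- sort_c(unlist(pr$map[matches[[s]]], use.names = FALSE))
      if (length(matches[[s]]) && !length(fin)) unprojected <- c(unprojected, s)
      matches[[s]] <- fin
    }
  } else {
    final_ids <- matched_ids
  }

  # group the final single entities by species and mark hits
  state <- fresh_analysis_state(f)
  by_species <- split(final_ids, vapply(final_ids, function(id) g$nodes[[id]]$species,
                                        character(1)))
  if (options$project) {
    by_species <- by_species[intersect(names(by_species), ref)]
    if (is.null(by_species[[ref]])) by_species[[ref]] <- character(0)
  }
  if (!length(by_species)) {
    # nothing mapped: still report the reference species' pathways (all k = 0)
    if (ref %in% f$species) by_species[[ref]] <- character(0)
  }

  n_by_species <- integer(0)
  for (sp in sort(names(by_species), method = "radix")) {
    ids <- by_species[[sp]]
    mains <- vapply(ids, function(id) g$nodes[[id]]$main_identifier, character(1))
    bg <- kb$background_sets[[sp]] %||% character(0)
    n_by_species[[sp]] <- length(unique(mains[mains %in% bg]))
    links <- collect_pathway_links(g, ids)
    for (id in ids) {
      key <- g$nodes[[id]]$main_identifier
      for (pid in links[[id]]) mark_hit(state, pid, key)
    }
  }

  rows <- compute_statistics(state, n_by_species)

  # render submitted:main matched pairs per row
  rev_map <- new_rec()   # final main identifier -> submitted identifiers
  for (s in names(matches)) {
    for (id in matches[[s]]) {
      main <- g$nodes[[id]]$main_identifier
      rev_map[[main]] <- c(rev_map[[main]], s)
    }
  }
  rows$matched_identifiers <- vapply(rows$found, function(found) {
    pairs <- unlist(lapply(found, function(main) {
      paste0(sort_c(rev_map[[main]] %||% character(0)), ":", main)
    }), use.names = FALSE)
    paste(pairs, collapse = ";")
  }, character(1))

  background_size <- lapply(names(n_by_species), function(sp) {
    as.integer(f$background[[sp]])
  })
  names(background_size) <- names(n_by_species)

  structure(
    list(
      rows = rows,
      mapping = mapping,
      not_found = not_found,
      unprojected = sort_c(unprojected),
      options = unclass(options),
      summary = list(
        sample_size_submitted = length(submitted),
        sample_size_mapped = as.integer(sum(n_by_species)),
        background_size = background_size
      )
    ),
    class = "analysis_result"
  )
}

# Canonical JSON serialisation: fixed key order, full numeric precision.
result_to_json <- function(result) {
  rows <- result$rows
  rows_out <- rows[, c("pathway_id", "pathway_name", "species", "entities_found",
                       "entities_total", "sample_mapped", "background",
                       "p_value", "fdr", "matched_identifiers"), drop = FALSE]
  rows_out$found <- lapply(rows$found, as.character)
  mapping <- result$mapping
  if (!length(mapping)) mapping <- structure(list(), names = character(0))
  payload <- list(
    summary = result$summary,
    options = result$options,
    rows = rows_out,
    mapping = mapping,
    not_found = as.character(result$not_found),
    unprojected = as.character(result$unprojected)
  )
  as.character(jsonlite::toJSON(payload, dataframe = "rows", auto_unbox = TRUE,
                                digits = NA, null = "null", na = "null"))
}

.result_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  chr <- function(v) as.character(unlist(v, use.names = FALSE))
  rows <- x$rows
  df <- data.frame(
    pathway_id = vapply(rows, function(r) r$pathway_id, character(1)),
    pathway_name = vapply(rows, function(r) r$pathway_name, character(1)),
    species = vapply(rows, function(r) r$species, character(1)),
    entities_found = vapply(rows, function(r) as.integer(r$entities_found), integer(1)),
    entities_total = vapply(rows, function(r) as.integer(r$entities_total), integer(1)),
    sample_mapped = vapply(rows, function(r) as.integer(r$sample_mapped), integer(1)),
    background = vapply(rows, function(r) as.integer(r$background), integer(1)),
    p_value = vapply(rows, function(r) as.numeric(r$p_value), numeric(1)),
    fdr = vapply(rows, function(r) as.numeric(r$fdr), numeric(1)),
    stringsAsFactors = FALSE
  )
  df$found <- lapply(rows, function(r) chr(r$found))
  df$matched_identifiers <- vapply(rows, function(r) r$matched_identifiers, character(1))
  mapping <- lapply(x$mapping, chr)
  structure(
    list(
      rows = df,
      mapping = mapping,
      not_found = chr(x$not_found),
      unprojected = chr(x$unprojected),
      options = list(project = isTRUE(x$options$project),
                     reference_species = x$options$reference_species,
                     include_interactors = isTRUE(x$options$include_interactors)),
      summary = list(
        sample_size_submitted = as.integer(x$summary$sample_size_submitted),
        sample_size_mapped = as.integer(x$summary$sample_size_mapped),
        background_size = lapply(x$summary$background_size, as.integer)
      )
    ),
    class = "analysis_result"
  )
}

.content_token <- function(json) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf), add = TRUE)
  writeLines(json, tf, sep = "", useBytes = TRUE)
  substr(unname(tools::md5sum(tf)), 1L, 20L)
}

#' Persist an analysis result under a content token
#'
#' The result is serialised to canonical JSON; the token is derived from a
#' content hash of that serialisation, so identical results (same input,
#' same options) always yield identical tokens, and any change to the
#' options or rows changes the token. Clients can later retrieve filtered
#' views by token without recomputation — see [filter_result()].
#'
#' @param result an `analysis_result`.
#' @param store writable directory (created if needed).
#' @return an `analysis_token` with fields `token` and `storage_path`.
#' @export
save_result <- function(result, store) {
  stopifnot(inherits(result, "analysis_result"))
  dir.create(store, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(store)) stop(sprintf("cannot create store '%s'", store), call. = FALSE)
  json <- result_to_json(result)
  token <- .content_token(json)
  path <- file.path(store, paste0(token, ".json"))
  con <- file(path, open = "wb")
  on.exit(close(con), add = TRUE)
  writeLines(json, con, sep = "\n", useBytes = TRUE)
  structure(list(token = token, storage_path = path), class = "analysis_token")
}

#' Load a persisted analysis result
#'
#' @param token an `analysis_token`, or a token string (then `store` is
#'   required).
#' @param store directory the result was saved into.
#' @return the deserialised `analysis_result`.
#' @export
load_result <- function(token, store = NULL) {
  path <- if (inherits(token, "analysis_token")) {
    token$storage_path
  } else {
    if (is.null(store)) stop("load_result(): store required with a token string",
                             call. = FALSE)
    file.path(store, paste0(token, ".json"))
  }
  if (!file.exists(path)) {
    stop(sprintf("unknown token: no result at '%s'", path), call. = FALSE)
  }
  .result_from_json(paste(readLines(path, warn = FALSE), collapse = "\n"))
}

#' Filter a persisted result server-side
#'
#' Applies the supplied criteria to the stored rows without recomputing any
#' statistic; the original p-value sort order is preserved and paging is
#' applied last.
#'
#' @param token an `analysis_token` or token string.
#' @param store directory for token strings (see [load_result()]).
#' @param species keep rows of this species only.
#' @param p_value_max keep rows with `p_value <= p_value_max`.
#' @param fdr_max keep rows with `fdr <= fdr_max`.
#' @param pathway_ids keep rows whose pathway id is in this set.
#' @param page,page_size 1-based pagination over the filtered rows.
#' @return data frame of the filtered rows.
#' @export
filter_result <- function(token, store = NULL, species = NULL, p_value_max = NULL,
                          fdr_max = NULL, pathway_ids = NULL, page = NULL,
                          page_size = NULL) {
  result <- load_result(token, store)
  rows <- result$rows
  keep <- rep(TRUE, nrow(rows))
  if (!is.null(species)) keep <- keep & rows$species %in% species
  if (!is.null(p_value_max)) keep <- keep & rows$p_value <= p_value_max
  if (!is.null(fdr_max)) keep <- keep & rows$fdr <= fdr_max
  if (!is.null(pathway_ids)) keep <- keep & rows$pathway_id %in% pathway_ids
  rows <- rows[keep, , drop = FALSE]
  if (!is.null(page)) {
    size <- page_size %||% 20L
    from <- (page - 1L) * size + 1L
    to <- min(page * size, nrow(rows))
    rows <- if (from > nrow(rows)) rows[0L, , drop = FALSE] else rows[from:to, , drop = FALSE]
  }
  rownames(rows) <- NULL
  rows
}

#' Write the result table as TSV
#'
#' Columns: `pathway_id`, `pathway_name`, `species`, `entities_found`,
#' `entities_total`, `sample_mapped`, `background`, `p_value`, `fdr`,
#' `matched_identifiers` (a semicolon-joined `submitted:main` list).
#' P-values are rendered with 6 significant digits.
#'
#' @param result an `analysis_result`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(result, path) {
  rows <- result$rows
  header <- c("pathway_id", "pathway_name", "species", "entities_found",
              "entities_total", "sample_mapped", "background", "p_value",
              "fdr", "matched_identifiers")
  lines <- paste(header, collapse = "\t")
  if (nrow(rows)) {
    body <- paste(rows$pathway_id, rows$pathway_name, rows$species,
                  rows$entities_found, rows$entities_total, rows$sample_mapped,
                  rows$background, sprintf("%.6g", rows$p_value),
                  sprintf("%.6g", rows$fdr), rows$matched_identifiers,
                  sep = "\t")
    lines <- c(lines, body)
  }
  con <- file(path, open = "wb")
  on.exit(close(con), add = TRUE)
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a result table written by [write_result_table()]
#'
#' @param path TSV file path.
#' @return data frame with the table's columns and types.
#' @export
read_result_table <- function(path) {
  utils::read.delim(path, sep = "\t", quote = "", check.names = FALSE,
                    na.strings = NULL, stringsAsFactors = FALSE,
                    colClasses = c(pathway_id = "character",
                                   pathway_name = "character",
                                   species = "character",
                                   entities_found = "integer",
                                   entities_total = "integer",
                                   sample_mapped = "integer",
                                   background = "integer",
                                   p_value = "numeric",
                                   fdr = "numeric",
                                   matched_identifiers = "character"))
}

#' @export
print.analysis_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<analysis_result> %d submitted, %d mapped, %d not found; %d pathway rows\n",
    s$sample_size_submitted, s$sample_size_mapped, length(x$not_found), nrow(x$rows)
  ))
  if (isTRUE(x$options$project)) {
    cat(sprintf("  projected to %s (%d unprojected)\n",
                x$options$reference_species, length(x$unprojected)))
  }
  top <- utils::head(x$rows[, c("pathway_id", "pathway_name", "entities_found",
                                "entities_total", "p_value", "fdr")], 5L)
  if (nrow(top)) print(top, row.names = FALSE)
  invisible(x)
}

#' @export
print.analysis_token <- function(x, ...) {
  cat(sprintf("<analysis_token> %s -> %s\n", x$token, x$storage_path))
  invisible(x)
}
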