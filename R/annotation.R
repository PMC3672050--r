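#' Read a cell-type marker table
#'
#' TSV with columns `gene_symbol` and `cell_type`
#' (`spermatogonia`, `spermatocytes`, `spermatids`, `leydig`, `ptm`,
#' `sertoli`); extra columns are kept. Symbols must be unique.
#'
#' @param path Path to the marker TSV.
#' @return A data.frame of markers.
#' @export
read_marker_table <- function(path) {
  mk <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_symbol", "cell_type") %in% colnames(mk)))
    stop("marker table needs columns gene_symbol, cell_type")
  mk$gene_symbol <- trimws(mk$gene_symbol)
  mk$cell_type <- trimws(tolower(mk$cell_type))
  bad <- setdiff(unique(mk$cell_type), .gw_cell_types)
  if (length(bad) > 0L)
    stop("unknown cell type(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(mk$gene_symbol))
    stop("duplicated gene symbols in the marker table")
  mk
}

.gw_cell_types <- c("spermatogonia", "spermatocytes", "spermatids",
                    "leydig", "ptm", "sertoli")

.gw_populations <- c("spermatogonia", "spermatocytes", "early_spermatids",
                     "late_spermatids", "somatic")

#' Packaged testicular cell-type marker table
#'
#' 39 published cell-specific markers of the adult mouse testis
#' (1 spermatogonia, 19 spermatocytes, 11 spermatids, 3 Leydig, 1
#' peritubular myoid, 4 Sertoli), each with the transcript cluster it was
#' identified in during the irradiation-recovery analysis (`cluster`
#' column).
#'
#' @return A 39-row marker data.frame (`gene_symbol`, `cell_type`,
#'   `cluster`).
#' @export
testis_markers <- function() {
  read_marker_table(system.file("extdata", "testis_markers.tsv",
                                package = "gapwave", mustWork = TRUE))
}

#' Map markers into transcript clusters
#'
#' Matches marker gene symbols against clustered transcript identifiers
#' (case-insensitively, whitespace stripped) and tabulates marker counts per
#' cluster and cell type. Markers absent from the clustered set are reported
#' in the `unmatched` attribute.
#'
#' @param markers Marker data.frame ([read_marker_table()],
#'   [testis_markers()]).
#' @param labels Named vector mapping transcript id to cluster index (e.g.
#'   `gw_clusters$labels`).
#' @return Integer matrix, clusters x cell types, with attribute
#'   `unmatched` (character vector of unmatched marker symbols).
#' @export
map_markers <- function(markers, labels) {
  key <- toupper(trimws(names(labels)))
  sym <- toupper(trimws(markers$gene_symbol))
  hit <- match(sym, key)
  found <- !is.na(hit)
  ks <- sort(unique(as.integer(labels)))
  tab <- table(factor(as.integer(labels)[hit[found]], levels = ks),
               factor(markers$cell_type[found], levels = .gw_cell_types))
  out <- matrix(as.integer(tab), nrow = length(ks),
                dimnames = list(cluster = as.character(ks),
                                cell_type = .gw_cell_types))
  attr(out, "unmatched") <- markers$gene_symbol[!found]
  out
}

#' Assign cell populations to transcript clusters
#'
#' For five clusters, combines marker evidence with the order in which the
#' irradiation-induced germ-cell gap reaches each population. The somatic
#' cluster is the one holding the majority of Leydig/PTM/Sertoli markers
#' (its profile shows an apparent rise while germ clusters dip, a
#' cellularity effect). The four germ clusters are ordered by the day of
#' their expression trough (the argmin of the median z-profile on the
#' sampled day grid, no interpolation): earliest trough = spermatogonia,
#' then spermatocytes (around pi day 17), early spermatids (trough around
#' day 24) and late spermatids (trough around day 27). If a germ cluster's
#' marker majority disagrees with the trough ordering the trough ordering
#' wins with a warning; identical trough days are broken by marker votes and
#' are an error if still tied.
#'
#' For `k != 5` only marker-majority labels are returned.
#'
#' @param profiles Per-cluster median z-profiles ([median_z_profiles()]),
#'   with `day_<d>` column names.
#' @param evidence Cluster x cell-type marker counts ([map_markers()]).
#' @return A `gw_celltypes`: list with `labels` (cluster index to
#'   population), `evidence`, and `extremum_day` (trough day for germ
#'   clusters, peak day for the somatic cluster).
#' @export
assign_cell_types <- function(profiles, evidence) {
  ks <- rownames(profiles)
  days <- as.integer(sub("^day_", "", colnames(profiles)))
  ev <- matrix(0L, length(ks), length(.gw_cell_types),
               dimnames = list(ks, .gw_cell_types))
  common <- intersect(rownames(evidence), ks)
  ev[common, colnames(evidence)] <- evidence[common, , drop = FALSE]

  if (length(ks) != 5L) {
    lab <- apply(ev, 1L, function(x) {
      if (all(x == 0L)) return(NA_character_)
      .gw_cell_types[which.max(x)]
    })
    return(structure(list(labels = lab, evidence = ev,
                          extremum_day = NULL),
                     class = "gw_celltypes"))
  }

  somatic_votes <- rowSums(ev[, c("leydig", "ptm", "sertoli"), drop = FALSE])
  peak_dev <- apply(profiles, 1L, function(z) z[which.max(abs(z))])
  if (any(somatic_votes > 0)) {
    somatic <- ks[which.max(somatic_votes)]
  } else {
    # no somatic markers found: fall back on the only cluster whose extreme
    # deviation is upward (the cellularity-driven apparent upregulation)
    up <- ks[peak_dev > 0]
    if (length(up) != 1L)
      stop("cannot identify the somatic cluster without marker evidence")
    somatic <- up
  }
  if (peak_dev[somatic] < 0)
    warning("somatic cluster profile does not rise; marker evidence kept")

  germ <- setdiff(ks, somatic)
  trough <- vapply(germ, function(k) days[which.min(profiles[k, ])],
                   integer(1))
  ord <- germ[order(trough)]
  if (anyDuplicated(trough)) {
    dup_days <- unique(trough[duplicated(trough)])
    for (dd in dup_days) {
      tied <- germ[trough == dd]
      pos <- which(ord %in% tied)
      stages <- c("spermatogonia", "spermatocytes", "spermatids",
                  "spermatids")[pos]
      votes <- ev[tied, unique(stages), drop = FALSE]
      if (length(unique(stages)) < 2L ||
          anyDuplicated(apply(votes, 1L, which.max)))
        stop("germ clusters tied on trough day ", dd,
             " and marker votes cannot break the tie")
      ord[pos] <- tied[order(-votes[, 1L])]
    }
  }
  labels <- stats::setNames(rep(NA_character_, 5L), ks)
  labels[somatic] <- "somatic"
  labels[ord] <- c("spermatogonia", "spermatocytes", "early_spermatids",
                   "late_spermatids")

  # marker-vote agreement check (trough ordering wins)
  germ_types <- c("spermatogonia", "spermatocytes", "spermatids")
  for (k in germ) {
    gv <- ev[k, germ_types]
    if (all(gv == 0L)) next
    majority <- germ_types[which.max(gv)]
    expected <- sub("^(early|late)_", "", labels[k])
    if (majority != expected)
      warning(sprintf(
        "cluster %s: marker majority (%s) disagrees with trough ordering (%s)",
        k, majority, labels[k]))
  }

  extremum <- vapply(ks, function(k) {
    if (k == somatic) days[which.max(profiles[k, ])]
    else days[which.min(profiles[k, ])]
  }, integer(1))
  structure(list(labels = labels, evidence = ev, extremum_day = extremum),
            class = "gw_celltypes")
}

#' @export
print.gw_celltypes <- function(x, ...) {
  cat("<gw_celltypes>\n")
  for (k in names(x$labels)) {
    ed <- if (!is.null(x$extremum_day)) {
      sprintf(" (extremum pi day %d)", x$extremum_day[[k]])
    } else ""
    cat(sprintf("  cluster %s -> %s%s\n", k, x$labels[[k]], ed))
  }
  invisible(x)
}

#' Write a cell-type assignment to JSON
#'
#' @param x A `gw_celltypes`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cell_types <- function(x, path) {
  jsonlite::write_json(
    list(labels = as.list(x$labels),
         extremum_day = as.list(x$extremum_day),
         evidence = as.data.frame(unclass(x$evidence))),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
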