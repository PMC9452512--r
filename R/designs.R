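#' Affinity-class multiplier table
#'
#' Binding sites are grouped into fold-weaker affinity classes relative to the
#' consensus site: strong/consensus (S, 1x), weak (W, 10x lower affinity),
#' weaker (W-, 20x), very weak (V, 50x), very-very weak (V-, 100x). The
#' non-specific class NS carries no specific binding and is excluded from
#' occupancy models.
#'
#' @return A data.frame with columns `class` and `multiplier`.
#' @export
affinity_class_table <- function() {
  data.frame(
    class = c("S", "W", "W-", "V", "V-"),
    multiplier = c(1, 10, 20, 50, 100),
    stringsAsFactors = FALSE
  )
}

#' Dissociation constant for an affinity class
#'
#' @param label character vector of affinity-class labels (S, W, W-, V, V-, NS).
#' @param consensus_kd consensus-site dissociation constant in nM (> 0).
#' @return K_d in nM; `NA` for NS sites (no specific binding).
#' @export
kd_for_class <- function(label, consensus_kd) {
  stopifnot(is.numeric(consensus_kd), all(consensus_kd > 0))
  tab <- affinity_class_table()
  out <- rep(NA_real_, length(label))
  known <- label %in% c(tab$class, "NS")
  if (any(!known)) {
    stop("unknown affinity class label(s): ",
         paste(unique(label[!known]), collapse = ", "))
  }
  idx <- match(label, tab$class)
  out[!is.na(idx)] <- consensus_kd * tab$multiplier[idx[!is.na(idx)]]
  out  # NS stays NA: site excluded from occupancy models
}

#' Construct a binding site
#'
#' Coordinates are 0-based, half-open: a site occupies basepairs
#' `[start, start + length)` on the target.
#'
#' @param site_id site identifier.
#' @param start 0-based offset on the target (>= 0).
#' @param length motif length in bp (default 9, Zif268-like zinc-finger motif;
#'   use 6 for Pho4-like E-boxes).
#' @param affinity_class one of S, W, W-, V, V-, NS.
#' @param kd dissociation constant in nM; if `NULL`, derived from the class
#'   via [kd_for_class()] and `consensus_kd`.
#' @param consensus_kd consensus K_d used when `kd` is derived.
#' @return An object of class `binding_site`.
#' @export
binding_site <- function(site_id, start, length = 9L, affinity_class = "S",
                         kd = NULL, consensus_kd = 10) {
  stopifnot(length(site_id) == 1, start >= 0, length >= 1)
  if (is.null(kd)) kd <- kd_for_class(affinity_class, consensus_kd)
  if (affinity_class != "NS" && (!is.finite(kd) || kd <= 0)) {
    stop("kd must be > 0 for specific sites (site ", site_id, ")")
  }
  structure(
    list(site_id = as.character(site_id), start = as.integer(start),
         length = as.integer(length), affinity_class = affinity_class,
         kd = as.numeric(kd)),
    class = "binding_site"
  )
}

#' Construct a binding-site cluster design
#'
#' A DNA target (default 90 bp) carrying zero or more positioned,
#' affinity-classed binding sites. Sites are stored sorted by start
#' coordinate; overlaps and spacings are derived from coordinates alone.
#'
#' @param target_id target identifier.
#' @param sites list of [binding_site()] objects.
#' @param target_length target length in bp (default 90).
#' @return An object of class `cluster_design` with fields `target_id`,
#'   `target_length`, `sites`, and `n_sites` (count of non-NS sites).
#' @export
cluster_design <- function(target_id, sites = list(), target_length = 90L) {
  stopifnot(length(target_id) == 1, target_length >= 1)
  if (length(sites) > 0) {
    stopifnot(all(vapply(sites, inherits, logical(1), "binding_site")))
    ids <- vapply(sites, `[[`, character(1), "site_id")
    if (anyDuplicated(ids)) {
      stop("duplicate site_id in design '", target_id, "': ",
           paste(ids[duplicated(ids)], collapse = ", "))
    }
    ends <- vapply(sites, function(s) s$start + s$length, numeric(1))
    if (any(ends > target_length)) {
      stop("site(s) extend beyond target_length in design '", target_id, "': ",
           paste(ids[ends > target_length], collapse = ", "))
    }
    sites <- sites[order(vapply(sites, `[[`, integer(1), "start"))]
  }
  classes <- vapply(sites, `[[`, character(1), "affinity_class")
  structure(
    list(target_id = as.character(target_id),
         target_length = as.integer(target_length),
         sites = sites,
         n_sites = sum(classes != "NS")),
    class = "cluster_design"
  )
}

#' @export
print.cluster_design <- function(x, ...) {
  cat(sprintf("<cluster_design '%s'> %d bp, %d specific site(s)\n",
              x$target_id, x$target_length, x$n_sites))
  for (s in x$sites) {
    cat(sprintf("  %-8s %3d-%-3d %-3s K_d=%s nM\n", s$site_id, s$start,
                s$start + s$length, s$affinity_class,
                formatC(s$kd, digits = 4)))
  }
  invisible(x)
}

#' Shared basepairs between two binding sites
#'
#' Length of the intersection of the half-open intervals
#' `[start, start + length)`; 0 when disjoint. Symmetric.
#'
#' @param a,b [binding_site()] objects.
#' @return integer number of shared bp.
#' @export
shared_basepairs <- function(a, b) {
  lo <- max(a$start, b$start)
  hi <- min(a$start + a$length, b$start + b$length)
  max(0L, as.integer(hi - lo))
}

#' Overlap fraction of a shared stretch relative to the motif
#'
#' @param shared shared bp (0..motif_length).
#' @param motif_length motif length in bp (> 0).
#' @return percent, rounded to the nearest integer for reporting.
#' @export
overlap_fraction <- function(shared, motif_length) {
  if (any(motif_length <= 0)) stop("invalid design: motif_length must be > 0")
  stopifnot(all(shared >= 0), all(shared <= motif_length))
  round(100 * shared / motif_length)
}

#' Spacing between two binding sites
#'
#' Gap in bp between the end of the first site and the start of the second
#' (the first must precede the second by start coordinate). Negative spacing
#' means the sites overlap; then `-spacing` equals [shared_basepairs()].
#'
#' @param a,b [binding_site()] objects, `a` preceding `b`.
#' @return integer gap in bp (may be negative).
#' @export
site_spacing <- function(a, b) {
  stopifnot(a$start <= b$start)
  as.integer(b$start - (a$start + a$length))
}

#' K_ds of a design's specific sites
#'
#' @param design a [cluster_design()].
#' @return numeric vector of K_d (nM) for the non-NS sites, in start order.
#' @export
site_kds <- function(design) {
  sp <- Filter(function(s) s$affinity_class != "NS", design$sites)
  vapply(sp, `[[`, numeric(1), "kd")
}

specific_sites <- function(design) {
  Filter(function(s) s$affinity_class != "NS", design$sites)
}

#' Read cluster designs from a CSV or JSON file
#'
#' CSV schema: one row per site with columns `target_id, site_id, start,
#' length, class, kd_nM` (kd_nM optional; derived from `class` and
#' `consensus_kd` when missing/NA). A row with an empty `site_id` declares a
#' site-free target. JSON mirrors the same records.
#'
#' @param path file path (`.csv` or `.json`).
#' @param consensus_kd consensus K_d used to derive missing K_ds.
#' @param target_length default target length for targets absent a
#'   `target_length` column.
#' @return list of [cluster_design()] objects (empty file -> empty list).
#' @export
read_designs <- function(path, consensus_kd = 10, target_length = 90L) {
  ext <- tolower(tools::file_ext(path))
  df <- if (ext == "json") {
    as.data.frame(jsonlite::fromJSON(path))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  if (nrow(df) == 0) return(list())
  need <- c("target_id", "site_id", "start", "length", "class")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) stop("design table missing column(s): ",
                             paste(miss, collapse = ", "))
  if (!"kd_nM" %in% names(df)) df$kd_nM <- NA_real_
  if (!"target_length" %in% names(df)) df$target_length <- target_length
  bad <- which(!is.na(df$site_id) & nzchar(df$site_id) &
                 (is.na(df$start) | is.na(df$length) | df$start < 0 | df$length < 1))
  if (length(bad) > 0) stop("malformed design row(s): ",
                            paste(bad, collapse = ", "))
  out <- lapply(split(df, factor(df$target_id, levels = unique(df$target_id))),
                function(d) {
    site_rows <- d[!is.na(d$site_id) & nzchar(d$site_id), , drop = FALSE]
    sites <- lapply(seq_len(nrow(site_rows)), function(i) {
      r <- site_rows[i, ]
      kd <- if (is.na(r$kd_nM)) NULL else r$kd_nM
      binding_site(r$site_id, r$start, r$length, r$class, kd = kd,
                   consensus_kd = consensus_kd)
    })
    cluster_design(d$target_id[1], sites, d$target_length[1])
  })
  unname(out)
}

#' Write cluster designs to CSV or JSON
#'
#' Round-trip stable with [read_designs()] on canonical form.
#'
#' @param designs list of [cluster_design()] objects.
#' @param path output path (`.csv` or `.json`).
#' @export
write_designs <- function(designs, path) {
  rows <- do.call(rbind, lapply(designs, function(d) {
    if (length(d$sites) == 0) {
      return(data.frame(target_id = d$target_id, site_id = "",
                        start = NA_integer_, length = NA_integer_,
                        class = "", kd_nM = NA_real_,
                        target_length = d$target_length))
    }
    do.call(rbind, lapply(d$sites, function(s) {
      data.frame(target_id = d$target_id, site_id = s$site_id,
                 start = s$start, length = s$length, class = s$affinity_class,
                 kd_nM = s$kd, target_length = d$target_length)
    }))
  }))
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(rows, path, dataframe = "rows", na = "null",
                         digits = NA, auto_unbox = TRUE)
  } else {
    utils::write.csv(rows, path, row.names = FALSE)
  }
  invisible(path)
}

# Fixed neutral backbone filler (documented constant): a low-complexity-free
# sequence with no Zif268 (GCGTGGGCG) or Pho4 E-box (CACGTG) match, repeated
# to target length. Placeholder motifs mark site positions by class.
.backbone_unit <- "ACTAGTCCATTAGATCTGAACTTCAGATCGATACCTGAATTGGTCATCTA"
.placeholder_motif <- function(length) {
  # Zif268 consensus-like placeholder, truncated or repeated to site length
  core <- "GCGTGGGCG"
  substr(strrep(core, ceiling(length / nchar(core))), 1, length)
}

#' Emit FASTA target sequences for a design library
#'
#' Each record is `target_length` bp: a fixed neutral backbone with a
#' placeholder motif written over each site interval (actual library
#' sequences are user input; sequence-to-affinity mapping is out of scope).
#'
#' @param designs list of [cluster_design()] objects.
#' @param path output FASTA path.
#' @return the path, invisibly.
#' @export
emit_fasta <- function(designs, path) {
  seqs <- vapply(designs, function(d) {
    bb <- substr(strrep(.backbone_unit,
                        ceiling(d$target_length / nchar(.backbone_unit))),
                 1, d$target_length)
    for (s in d$sites) {
      substr(bb, s$start + 1, s$start + s$length) <- .placeholder_motif(s$length)
    }
    bb
  }, character(1))
  names(seqs) <- vapply(designs, `[[`, character(1), "target_id")
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
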