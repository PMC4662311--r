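#' Read a genotype table from a wide two-columns-per-locus CSV
#'
#' The dialect follows the common survey-tool layout: the first column is the
#' sample id, followed by an even number of allele columns, two per locus.
#' The locus name is taken from the first column of each pair. Missing
#' genotypes are coded \code{0,0}; a half-missing pair (one zero) is a format
#' error, as is any non-integer allele.
#'
#' @param path CSV file path.
#' @return genotype_table.
#' @export
read_genotype_table <- function(path) {
  if (!file.exists(path)) stop("genotype file not found: ", path)
  raw <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 3 || (ncol(raw) - 1) %% 2 != 0)
    stop("format error: expected an even number of allele columns (two per locus), got ",
         ncol(raw) - 1)
  loci <- names(raw)[seq(2, ncol(raw), by = 2)]
  rows <- list()
  for (j in seq_along(loci)) {
    a <- raw[[2 * j]]
    b <- raw[[2 * j + 1]]
    if (!is.numeric(a) || !is.numeric(b))
      stop("format error: non-integer allele at locus ", loci[j])
    half <- xor(a == 0, b == 0)
    if (any(half))
      stop("format error: half-missing genotype (allele paired with 0) at locus ",
           loci[j], ", sample ", raw[[1]][which(half)[1]])
    rows[[j]] <- data.frame(sample_id = as.character(raw[[1]]),
                            locus_id = loci[j],
                            allele_a = ifelse(a == 0, NA_integer_, as.integer(a)),
                            allele_b = ifelse(b == 0, NA_integer_, as.integer(b)),
                            stringsAsFactors = FALSE)
  }
  genotype_table(do.call(rbind, rows))
}

#' Write a genotype table to the two-columns-per-locus CSV dialect
#'
#' Inverse of \code{\link{read_genotype_table}}; missing genotypes are written
#' as \code{0,0}. Output is bit-stable given a fixed table.
#'
#' @param gt genotype_table.
#' @param path output CSV path.
#' @export
write_genotype_table <- function(gt, path) {
  stopifnot(inherits(gt, "genotype_table"))
  samples <- unique(gt$sample_id)
  loci <- sort(unique(gt$locus_id))
  out <- data.frame(sample_id = samples, stringsAsFactors = FALSE)
  for (l in loci) {
    rows <- gt[gt$locus_id == l, ]
    rows <- rows[match(samples, rows$sample_id), ]
    a <- ifelse(is.na(rows$allele_a), 0L, rows$allele_a)
    b <- ifelse(is.na(rows$allele_b), 0L, rows$allele_b)
    out[[l]] <- a
    out[[paste0(l, ".2")]] <- b
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read replicate-PCR allele calls
#'
#' CSV with columns \code{scat_id, pcr_id, locus_id, allele_a, allele_b}.
#' \code{0,0} codes a failed PCR; a call with \code{allele_a == allele_b}
#' means only that allele was observed (indistinguishable from a true
#' homozygote in fragment analysis); a half-zero pair is a format error.
#'
#' @param path CSV path.
#' @return replicate_set: data.frame with the same columns, failed calls as
#'   NA,NA, unordered pairs canonicalized, (scat_id, pcr_id, locus_id) unique.
#' @export
read_replicate_set <- function(path) {
  if (!file.exists(path)) stop("replicate file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  replicate_set(df)
}

#' Construct/validate a replicate set
#' @param df data.frame with scat_id, pcr_id, locus_id, allele_a, allele_b
#'   (0,0 or NA,NA = failed PCR).
#' @return replicate_set data.frame.
#' @export
replicate_set <- function(df) {
  need <- c("scat_id", "pcr_id", "locus_id", "allele_a", "allele_b")
  if (!all(need %in% names(df)))
    stop("replicate set needs columns: ", paste(need, collapse = ", "))
  df <- as.data.frame(df)[need]
  df$scat_id <- as.character(df$scat_id)
  df$pcr_id <- as.character(df$pcr_id)
  df$locus_id <- as.character(df$locus_id)
  for (col in c("allele_a", "allele_b")) {
    a <- df[[col]]
    if (any(!is.na(a) & a != round(a))) stop("non-integer allele in ", col)
    a[!is.na(a) & a == 0] <- NA
    df[[col]] <- as.integer(a)
  }
  half <- xor(is.na(df$allele_a), is.na(df$allele_b))
  if (any(half)) stop("half-missing replicate call (allele paired with 0)")
  if (anyDuplicated(df[c("scat_id", "pcr_id", "locus_id")]))
    stop("duplicated (scat_id, pcr_id, locus_id) replicate rows")
  swap <- !is.na(df$allele_a) & df$allele_a > df$allele_b
  tmp <- df$allele_a[swap]
  df$allele_a[swap] <- df$allele_b[swap]
  df$allele_b[swap] <- tmp
  class(df) <- c("replicate_set", "data.frame")
  df
}

#' Write a replicate set (failed PCRs coded 0,0)
#' @param rs replicate_set.
#' @param path output CSV path.
#' @export
write_replicate_set <- function(rs, path) {
  out <- as.data.frame(rs)
  out$allele_a[is.na(out$allele_a)] <- 0L
  out$allele_b[is.na(out$allele_b)] <- 0L
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- geometry ----

read_geojson_geoms <- function(path, type) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features
           else list(gj)
  geoms <- list()
  for (f in feats) {
    g <- if (!is.null(f$geometry)) f$geometry else f
    if (!identical(g$type, type)) next
    if (type == "LineString") {
      m <- do.call(rbind, lapply(g$coordinates, function(p)
        c(x = as.numeric(p[[1]]), y = as.numeric(p[[2]]))))
    } else if (type == "Polygon") {
      ring <- g$coordinates[[1]]  # exterior ring only
      m <- do.call(rbind, lapply(ring, function(p)
        c(x = as.numeric(p[[1]]), y = as.numeric(p[[2]]))))
    } else stop("unsupported geometry type: ", type)
    geoms[[length(geoms) + 1]] <- m
  }
  geoms
}

read_csv_geoms <- function(path, id_col) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c(id_col, "x", "y")
  if (!all(need %in% names(df)))
    stop("geometry CSV needs columns: ", paste(need, collapse = ", "))
  lapply(split(df, df[[id_col]]),
         function(d) cbind(x = d$x, y = d$y))
}

#' Read survey geometry: transects, habitat polygon, scat detections
#'
#' Transects and habitat are GeoJSON (LineString / Polygon features; only
#' exterior polygon rings are used) or, as a fallback, vertex CSVs with
#' columns \code{transect_id,x,y} / \code{polygon_id,x,y} in path order.
#' Coordinates must be planar meters (already projected); no CRS handling is
#' performed. Detections are a CSV \code{scat_id,x,y,occasion} with 1-based
#' integer occasions.
#'
#' @param path_transects,path_habitat,path_detections file paths; habitat
#'   and detections may be NULL (e.g. simulation-only geometry).
#' @return survey_geometry: list(transects, habitat, detections).
#' @export
read_survey <- function(path_transects, path_habitat = NULL,
                        path_detections = NULL) {
  read_geoms <- function(path, type, id_col) {
    if (grepl("\\.(geojson|json)$", path, ignore.case = TRUE))
      read_geojson_geoms(path, type)
    else read_csv_geoms(path, id_col)
  }
  transects <- read_geoms(path_transects, "LineString", "transect_id")
  if (length(transects) == 0) stop("no transect polylines found in ", path_transects)
  habitat <- if (!is.null(path_habitat))
    read_geoms(path_habitat, "Polygon", "polygon_id") else NULL
  detections <- if (!is.null(path_detections)) {
    if (!file.exists(path_detections))
      stop("detections file not found: ", path_detections)
    df <- read.csv(path_detections, stringsAsFactors = FALSE)
    need <- c("scat_id", "x", "y", "occasion")
    if (!all(need %in% names(df)))
      stop("detections CSV needs columns: ", paste(need, collapse = ", "))
    df
  } else data.frame(scat_id = character(), x = numeric(), y = numeric(),
                    occasion = integer(), stringsAsFactors = FALSE)
  survey_geometry(transects, habitat, detections)
}

#' Construct/validate survey geometry
#'
#' @param transects list of 2-column (x, y) vertex matrices, planar meters.
#' @param habitat list of polygon exterior-ring vertex matrices, or NULL.
#' @param detections data.frame(scat_id, x, y, occasion).
#' @return survey_geometry object.
#' @export
survey_geometry <- function(transects, habitat = NULL,
                            detections = data.frame(scat_id = character(),
                                                    x = numeric(), y = numeric(),
                                                    occasion = integer())) {
  for (m in c(transects, habitat))
    if (!all(is.finite(m))) stop("non-finite coordinate in geometry")
  detections <- as.data.frame(detections)
  if (nrow(detections)) {
    if (!all(is.finite(detections$x)) || !all(is.finite(detections$y)))
      stop("non-finite detection coordinate")
    occ <- detections$occasion
    if (any(is.na(occ)) || any(occ != round(occ)) || any(occ < 1))
      stop("occasions must be positive (1-based) integers")
    detections$occasion <- as.integer(occ)
    ref <- if (!is.null(habitat)) do.call(rbind, habitat)
           else do.call(rbind, transects)
    pad <- 10000  # 10 km: beyond this a CRS mix-up is the likely cause
    bad <- detections$x < min(ref[, 1]) - pad | detections$x > max(ref[, 1]) + pad |
           detections$y < min(ref[, 2]) - pad | detections$y > max(ref[, 2]) + pad
    if (any(bad))
      stop("detection ", detections$scat_id[which(bad)[1]],
           " lies >10 km outside the survey bounding box; check projection")
  }
  structure(list(transects = transects, habitat = habitat,
                 detections = detections),
            class = "survey_geometry")
}

#' @export
print.survey_geometry <- function(x, ...) {
  cat("survey_geometry:", length(x$transects), "transect(s),",
      if (is.null(x$habitat)) "no habitat polygon,"
      else paste(length(x$habitat), "habitat polygon(s),"),
      nrow(x$detections), "detections\n")
  invisible(x)
}

#' Write polylines or polygons as GeoJSON
#' @param geoms list of vertex matrices.
#' @param path output path.
#' @param type "LineString" or "Polygon".
#' @export
write_geojson <- function(geoms, path, type = c("LineString", "Polygon")) {
  type <- match.arg(type)
  feat <- lapply(geoms, function(m) {
    coords <- lapply(seq_len(nrow(m)), function(i) c(m[i, 1], m[i, 2]))
    if (type == "Polygon") {
      # close the ring
      if (!isTRUE(all.equal(coords[[1]], coords[[length(coords)]])))
        coords <- c(coords, coords[1])
      coords <- list(coords)
    }
    list(type = "Feature", properties = NULL,
         geometry = list(type = type, coordinates = coords))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feat),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Write a detections CSV (scat_id, x, y, occasion, and any extra columns)
#' @param detections data.frame.
#' @param path output path.
#' @export
write_detections <- function(detections, path) {
  write.csv(as.data.frame(detections), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
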