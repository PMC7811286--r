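#' Create an occurrence set
#'
#' Point records with a role tag separating calibration records (native-range
#' data the model is fitted on) from independent records (detections in the
#' invaded region, used only for testing predictions). A free-text provenance
#' log accumulates the filters applied to the set.
#'
#' @param df data.frame with columns `species`, `lon`, `lat` and optionally
#'   `country` and `role`; missing `role` defaults to `"calibration"`.
#' @param provenance character vector describing how the set was produced.
#' @return data.frame of class `occ_set` with a `provenance` attribute.
#' @export
occurrence_set <- function(df, provenance = character()) {
  df <- as.data.frame(df)
  need <- c("species", "lon", "lat")
  if (!all(need %in% names(df))) {
    stop("occurrence data needs columns: ", paste(need, collapse = ", "))
  }
  if (is.null(df$country)) df$country <- rep(NA_character_, nrow(df))
  if (is.null(df$role)) df$role <- rep("calibration", nrow(df))
  if (!all(df$role %in% c("calibration", "independent"))) {
    stop("role must be 'calibration' or 'independent'")
  }
  ok_lon <- is.na(df$lon) | (df$lon >= -180 & df$lon <= 180)
  ok_lat <- is.na(df$lat) | (df$lat >= -90 & df$lat <= 90)
  if (!all(ok_lon) || !all(ok_lat)) stop("coordinates out of range")
  rownames(df) <- NULL
  structure(df, provenance = provenance, class = c("occ_set", "data.frame"))
}

#' @export
print.occ_set <- function(x, ...) {
  cat(sprintf("<occ_set> %d records (%d calibration, %d independent)\n",
              nrow(x), sum(x$role == "calibration"),
              sum(x$role == "independent")))
  for (p in attr(x, "provenance")) cat("  - ", p, "\n", sep = "")
  if (nrow(x)) print(utils::head(as.data.frame(x), 6L))
  invisible(x)
}

occ_provenance <- function(x) attr(x, "provenance")

add_provenance <- function(x, msg) {
  attr(x, "provenance") <- c(attr(x, "provenance"), msg)
  x
}

#' Read / write occurrence CSV
#'
#' @param path CSV path with columns `species, lon, lat, country, role`.
#' @return an `occ_set` ([read_occurrences()]) or `path` invisibly.
#' @export
read_occurrences <- function(path) {
  occurrence_set(utils::read.csv(path, stringsAsFactors = FALSE),
                 provenance = paste("read from", basename(path)))
}

#' @rdname read_occurrences
#' @param occ an `occ_set`.
#' @export
write_occurrences <- function(occ, path) {
  utils::write.csv(as.data.frame(occ), path, row.names = FALSE)
  invisible(path)
}

#' Clean occurrence records
#'
#' Removes records with missing coordinates, exact duplicates (same species
#' and coordinates after rounding to 6 decimal places), records falling in no
#' country ("at sea"), and records whose declared country disagrees with the
#' country they fall in. Countries are given as an integer-ID country raster
#' (`NA` = sea); see [voronoi_countries()] for the synthetic generator.
#'
#' @param occ an `occ_set`; the `country` column holds country ids matching
#'   the raster's values (records with `NA` country skip the declared-country
#'   consistency check but must still fall on land).
#' @param countries `raster_grid` of integer country ids, `NA` over sea.
#' @return cleaned `occ_set`; provenance records counts removed per rule.
#' @export
clean_occurrences <- function(occ, countries) {
  stopifnot(inherits(occ, "occ_set"), is_raster_grid(countries))
  if (all(is.na(countries$values))) stop("country raster is empty (all sea)")
  df <- as.data.frame(occ)
  n0 <- nrow(df)
  if (n0 == 0L) {
    return(add_provenance(occ, "clean: empty input"))
  }

  miss <- is.na(df$lon) | is.na(df$lat)
  df <- df[!miss, , drop = FALSE]

  key <- paste(df$species, round(df$lon, 6), round(df$lat, 6))
  dup <- duplicated(key)
  df <- df[!dup, , drop = FALSE]

  cell <- cell_from_lonlat(countries, df$lon, df$lat)
  cid <- rep(NA_real_, nrow(df))
  cid[!is.na(cell)] <- as.vector(t(countries$values))[cell[!is.na(cell)]]
  at_sea <- is.na(cid)
  df_land <- df[!at_sea, , drop = FALSE]
  cid <- cid[!at_sea]

  declared <- suppressWarnings(as.numeric(df_land$country))
  wrong <- !is.na(declared) & declared != cid
  df_ok <- df_land[!wrong, , drop = FALSE]

  out <- occurrence_set(df_ok, provenance = occ_provenance(occ))
  add_provenance(out, sprintf(
    "clean: %d -> %d (removed %d missing-coordinate, %d duplicate, %d at-sea, %d wrong-country)",
    n0, nrow(df_ok), sum(miss), sum(dup), sum(at_sea), sum(wrong)
  ))
}

# great-circle km between two coordinate matrices (haversine, R = 6371 km)
haversine_km <- function(p, q) {
  geosphere::distHaversine(p, q, r = 6371)
}

#' Distance-based spatial thinning
#'
#' Greedy thinning: records are shuffled by `seed`, then scanned once,
#' keeping each record only if it is at least `min_km` (great-circle) from
#' every record kept so far. The result is a subset whose pairwise distances
#' are all >= `min_km`, and it is maximal under the scan order (every removed
#' record is within `min_km` of a kept one). The 50-km rule used to reduce
#' spatial autocorrelation in the native range corresponds to
#' `min_km = 50`.
#'
#' @param occ an `occ_set`.
#' @param min_km minimum allowed pairwise distance in kilometers (> 0).
#' @param seed integer seed controlling the scan order.
#' @return thinned `occ_set` (same seed, same result).
#' @export
thin_distance <- function(occ, min_km, seed = 1L) {
  stopifnot(inherits(occ, "occ_set"), min_km > 0)
  df <- as.data.frame(occ)
  n <- nrow(df)
  if (n <= 1L) {
    return(add_provenance(occ, sprintf("thin_distance(%g km): %d -> %d",
                                       min_km, n, n)))
  }
  ord <- local_rng(seed, "thin_distance", function() sample.int(n))
  keep <- integer(0)
  for (i in ord) {
    if (length(keep) == 0L) {
      keep <- i
      next
    }
    d <- haversine_km(c(df$lon[i], df$lat[i]),
                      cbind(df$lon[keep], df$lat[keep]))
    if (all(d >= min_km)) keep <- c(keep, i)
  }
  keep <- sort(keep)
  out <- occurrence_set(df[keep, , drop = FALSE],
                        provenance = occ_provenance(occ))
  add_provenance(out, sprintf("thin_distance(%g km, seed %d): %d -> %d",
                              min_km, seed, n, length(keep)))
}

#' Country-density thinning
#'
#' Randomly subsamples records in over-sampled countries down to explicit
#' target counts, leaving all other countries untouched. This reproduces the
#' density-equalization step in which the densest-sampled countries are
#' reduced (e.g. 30, 6 and 5 records down to 6, 2 and 2) to match the
#' sampling density of the rest of the native range.
#'
#' @param occ an `occ_set`.
#' @param targets named numeric vector: `country id -> target count`; each
#'   target must not exceed the country's current count.
#' @param seed integer seed for the subsampling.
#' @return thinned `occ_set`.
#' @export
thin_country_density <- function(occ, targets, seed = 1L) {
  stopifnot(inherits(occ, "occ_set"), length(targets) >= 1L)
  df <- as.data.frame(occ)
  n <- nrow(df)
  keep <- rep(TRUE, n)
  picks <- local_rng(seed, "thin_country", function() {
    lapply(names(targets), function(cty) {
      idx <- which(!is.na(df$country) & as.character(df$country) == cty)
      tgt <- targets[[cty]]
      if (tgt > length(idx)) {
        stop(sprintf("target %d exceeds available %d records for country %s",
                     tgt, length(idx), cty))
      }
      sort(sample(idx, tgt))
    })
  })
  for (j in seq_along(targets)) {
    cty <- names(targets)[j]
    idx <- which(!is.na(df$country) & as.character(df$country) == cty)
    keep[idx] <- FALSE
    keep[picks[[j]]] <- TRUE
  }
  out <- occurrence_set(df[keep, , drop = FALSE],
                        provenance = occ_provenance(occ))
  add_provenance(out, sprintf(
    "thin_country_density(%s, seed %d): %d -> %d",
    paste(names(targets), targets, sep = "=", collapse = ", "),
    seed, n, sum(keep)
  ))
}

# Run `fn` under a temporary RNG state seeded from (seed, label), restoring
# the caller's RNG afterwards. All package randomness goes through this, so a
# single master seed plus stage labels gives independent, reproducible
# substreams.
local_rng <- function(seed, label, fn) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  sub <- (as.numeric(seed) * 48271 +
            sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))) %% 2147483647
  set.seed(as.integer(sub))
  fn()
}
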