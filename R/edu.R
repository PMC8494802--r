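#' Simulate a two-channel (DAPI, EdU) blastomere image
#'
#' Renders a primary nucleus and optional micronuclei as discs on a flat
#' background: the DAPI channel is proportional to DNA density within each
#' structure, the EdU channel to the per-structure replication rate.
#' Intensities are in arbitrary units on a 16-bit-like scale.
#'
#' @param dim image dimensions `c(rows, cols)`.
#' @param pn list `(x, y, r)` of the primary nucleus disc (pixels).
#' @param mn list of micronucleus discs, each `(x, y, r)`.
#' @param dapi_pn,dapi_mn DAPI intensity (DNA density) per structure.
#' @param edu_rate_pn,edu_rate_mn EdU incorporation rate per structure.
#' @param background additive background intensity in both channels.
#' @param noise_sd standard deviation of Gaussian noise (0 = noiseless).
#' @param seed integer seed.
#' @return list with matrices `dapi` and `edu`, integer label matrix
#'   `masks` (1 = primary nucleus, 2, 3, ... = micronuclei, 0 =
#'   background) and `background_region` `(x, y, w, h)` guaranteed free of
#'   foreground.
#' @export
simulate_edu_image <- function(dim = c(128, 128),
                               pn = list(x = 48, y = 64, r = 22),
                               mn = list(list(x = 92, y = 64, r = 7)),
                               dapi_pn = 400, dapi_mn = 400,
                               edu_rate_pn = 300, edu_rate_mn = 300,
                               background = 40, noise_sd = 0, seed = 1) {
  set.seed(seed)
  structs <- c(list(pn), mn)
  for (i in seq_along(structs)) for (j in seq_len(i - 1)) {
    a <- structs[[i]]; b <- structs[[j]]
    if (sqrt((a$x - b$x)^2 + (a$y - b$y)^2) < a$r + b$r)
      stop("overlapping nucleus/micronucleus structures")
  }
  for (s in structs)
    if (s$x - s$r < 1 || s$y - s$r < 1 || s$x + s$r > dim[2] ||
        s$y + s$r > dim[1])
      stop("structure outside image bounds")
  xs <- matrix(rep(seq_len(dim[2]), each = dim[1]), dim[1])
  ys <- matrix(rep(seq_len(dim[1]), dim[2]), dim[1])
  masks <- matrix(0L, dim[1], dim[2])
  dapi <- matrix(background, dim[1], dim[2])
  edu <- matrix(background, dim[1], dim[2])
  dapi_v <- c(dapi_pn, rep_len(dapi_mn, length(mn)))
  edu_v <- c(edu_rate_pn, rep_len(edu_rate_mn, length(mn)))
  for (i in seq_along(structs)) {
    s <- structs[[i]]
    inside <- (xs - s$x)^2 + (ys - s$y)^2 <= s$r^2
    masks[inside] <- i
    dapi[inside] <- background + dapi_v[i]
    edu[inside] <- background + edu_v[i]
  }
  if (noise_sd > 0) {
    dapi <- pmax(dapi + stats::rnorm(length(dapi), 0, noise_sd), 0)
    edu <- pmax(edu + stats::rnorm(length(edu), 0, noise_sd), 0)
  }
  bw <- max(8, floor(min(dim) / 8))
  bg_region <- c(x = 1, y = 1, w = bw, h = bw)
  if (any(masks[seq_len(bw), seq_len(bw)] > 0))
    bg_region <- c(x = dim[2] - bw + 1, y = 1, w = bw, h = bw)
  list(dapi = dapi, edu = edu, masks = masks, background_region = bg_region)
}

#' Segment nuclei and micronuclei from a DAPI image
#'
#' Otsu thresholding of the DAPI channel followed by hole filling and
#' watershed splitting of touching objects (via the distance transform);
#' the largest object is labeled the primary nucleus and every other
#' DAPI-positive object of at least `min_area` pixels a micronucleus. A
#' manually refined mask can be supplied via `override` in place of the
#' automatic segmentation.
#'
#' @param dapi numeric matrix (single best focal plane).
#' @param min_area minimum object area in pixels.
#' @param override optional integer label matrix replacing the automatic
#'   segmentation (1 = primary, >1 = micronuclei).
#' @return data frame (label, id, area) plus attribute `masks`, an integer
#'   label matrix; zero rows when no foreground is found.
#' @export
segment_nuclei <- function(dapi, min_area = 12, override = NULL) {
  if (is.null(override)) {
    rng <- range(dapi)
    if (diff(rng) < 1e-9) {
      labels <- matrix(0L, nrow(dapi), ncol(dapi))
    } else {
      img <- EBImage::Image((dapi - rng[1]) / diff(rng))
      thr <- EBImage::otsu(img)
      bw <- img > thr
      bw <- EBImage::fillHull(bw)
      labels <- EBImage::watershed(EBImage::distmap(bw))
      labels <- EBImage::imageData(labels)
    }
  } else {
    labels <- override
  }
  ids <- setdiff(sort(unique(as.integer(labels))), 0L)
  areas <- vapply(ids, function(i) sum(labels == i), numeric(1))
  keep <- areas >= min_area
  ids <- ids[keep]; areas <- areas[keep]
  if (length(ids) == 0) {
    out <- data.frame(label = character(), id = integer(), area = numeric())
    attr(out, "masks") <- matrix(0L, nrow(dapi), ncol(dapi))
    return(out)
  }
  ord <- order(areas, decreasing = TRUE)
  ids <- ids[ord]; areas <- areas[ord]
  relab <- matrix(0L, nrow(dapi), ncol(dapi))
  for (k in seq_along(ids)) relab[labels == ids[k]] <- k
  out <- data.frame(label = c("primary",
                              rep("micronucleus", length(ids) - 1)),
                    id = seq_along(ids), area = areas,
                    stringsAsFactors = FALSE)
  attr(out, "masks") <- relab
  out
}

#' Measure EdU incorporation density in micronuclei vs the primary nucleus
#'
#' Per structure, density = (mean EdU - background EdU) / (mean DAPI -
#' background DAPI), with the background taken as the mean intensity of a
#' rectangular region near the nuclei. Negative background-subtracted
#' densities are clamped to 0 with a warning. The measurement is retained
#' only when the primary nucleus shows ongoing replication —
#' background-subtracted EdU intensity at least `gate` (10 a.u. by
#' default); otherwise the ratio is `NA` with a reason.
#'
#' @param nuclei output of [segment_nuclei()] (with its `masks`
#'   attribute).
#' @param edu,dapi numeric image matrices.
#' @param background_region `c(x, y, w, h)` rectangle (1-based, columns x,
#'   rows y) disjoint from all masks.
#' @param gate minimum background-subtracted primary-nucleus EdU intensity
#'   in arbitrary units.
#' @return data frame with one row per micronucleus: `mn_id`,
#'   `mn_edu_density`, `pn_edu_density`, `ratio`, `pn_edu_raw`,
#'   `pn_replicating`, `reason`.
#' @export
measure_edu <- function(nuclei, edu, dapi, background_region, gate = 10) {
  masks <- attr(nuclei, "masks")
  if (is.null(masks)) stop("nuclei must carry a masks attribute")
  r <- background_region
  rows <- r["y"]:(r["y"] + r["h"] - 1)
  cols <- r["x"]:(r["x"] + r["w"] - 1)
  if (any(masks[rows, cols] > 0))
    stop("background region overlaps a segmented structure")
  bg_e <- mean(edu[rows, cols])
  bg_d <- mean(dapi[rows, cols])
  density <- function(id) {
    m <- masks == id
    de <- mean(edu[m]) - bg_e
    dd <- mean(dapi[m]) - bg_d
    if (dd <= 0) return(NA_real_)
    val <- de / dd
    if (val < 0) {
      warning("negative background-subtracted density clamped to 0")
      val <- 0
    }
    val
  }
  pn_id <- nuclei$id[nuclei$label == "primary"]
  if (length(pn_id) == 0) stop("no primary nucleus in segmentation")
  pn_raw <- mean(edu[masks == pn_id]) - bg_e
  pn_dens <- density(pn_id)
  replicating <- is.finite(pn_raw) && pn_raw >= gate
  mn_ids <- nuclei$id[nuclei$label == "micronucleus"]
  if (length(mn_ids) == 0)
    return(data.frame(mn_id = integer(), mn_edu_density = numeric(),
                      pn_edu_density = numeric(), ratio = numeric(),
                      pn_edu_raw = numeric(), pn_replicating = logical(),
                      reason = character()))
  out <- lapply(mn_ids, function(id) {
    mn_dens <- density(id)
    data.frame(mn_id = id, mn_edu_density = mn_dens,
               pn_edu_density = pn_dens,
               ratio = if (replicating && is.finite(pn_dens) &&
                           pn_dens > 0) mn_dens / pn_dens else NA_real_,
               pn_edu_raw = pn_raw, pn_replicating = replicating,
               reason = if (replicating) ""
                        else "primary nucleus below EdU gate",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write a two-channel image as 16-bit TIFF files
#'
#' @param img list with `dapi` and `edu` matrices (arbitrary units).
#' @param dapi_file,edu_file output paths.
#' @param scale full-scale intensity mapped to 65535.
#' @export
write_edu_tiff <- function(img, dapi_file, edu_file, scale = 1000) {
  tiff::writeTIFF(pmin(img$dapi / scale, 1), dapi_file,
                  bits.per.sample = 16)
  tiff::writeTIFF(pmin(img$edu / scale, 1), edu_file, bits.per.sample = 16)
  invisible(c(dapi_file, edu_file))
}
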