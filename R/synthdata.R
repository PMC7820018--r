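#' Variance components of the two-way consistency model
#'
#' Ground truth for the simulation model \eqn{y_{ij} = \mu + s_i + r_j +
#' e_{ij}} with independent zero-mean normal subject effects \eqn{s_i}
#' (variance `subject_var`), systematic per-column rater/protocol offsets
#' \eqn{r_j} (variance `rater_var`) and residual noise \eqn{e_{ij}} (variance
#' `residual_var`), all in squared feature units. Under this model the
#' consistency ICC(3,1) equals \eqn{\sigma_s^2 / (\sigma_s^2 + \sigma_e^2)}:
#' the rater variance cancels, which is exactly what a consistency (rather
#' than absolute-agreement) coefficient is designed to do.
#'
#' @param subject_var,rater_var,residual_var non-negative variances.
#' @return an object of class \code{variance_components}.
#' @export
variance_components <- function(subject_var, rater_var = 0, residual_var = 0) {
  for (nm in c("subject_var", "rater_var", "residual_var")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop("'", nm, "' must be a single non-negative variance")
  }
  structure(list(subject_var = subject_var, rater_var = rater_var,
                 residual_var = residual_var),
            class = "variance_components")
}

#' @rdname variance_components
#' @export
true_icc <- function(components) {
  tot <- components$subject_var + components$residual_var
  if (tot <= 0) return(NA_real_)
  components$subject_var / tot
}

#' Variance components with a prescribed true ICC
#'
#' Convenience constructor: unit total subject+residual variance split so the
#' consistency ICC equals `icc`.
#'
#' @param icc target consistency ICC in [0, 1].
#' @param rater_var systematic per-column offset variance.
#' @export
components_for_icc <- function(icc, rater_var = 0.25) {
  stopifnot(is.numeric(icc), icc >= 0, icc <= 1)
  variance_components(subject_var = icc, rater_var = rater_var,
                      residual_var = 1 - icc)
}

#' Study layouts
#'
#' A layout names the acquisition design: which scanners, which protocols
#' (tube current in mA, reconstruction slice thickness in mm, in-plane voxel
#' size in mm, contrast flag), how many timepoints and subjects. Three
#' presets mirror the designed experiments: a multi-protocol image-quality
#' phantom study (6 protocols x 3 scanners x 2 timepoints = 36 scan slots,
#' one physical phantom), a clinical cohort (104 subjects, 3 protocols on one
#' scanner) and a test-retest cohort (32 subjects x 2 scans).
#'
#' @param scanners character vector of scanner labels.
#' @param protocols data.frame with columns `name`, `mA`, `thickness_mm`,
#'   `inplane_mm`, `contrast`.
#' @param timepoints integer number of timepoints (test/retest = 2).
#' @param subjects integer number of subjects.
#' @return an object of class \code{study_layout}.
#' @export
study_layout <- function(scanners, protocols, timepoints, subjects) {
  stopifnot(is.character(scanners), length(scanners) >= 1L)
  need <- c("name", "mA", "thickness_mm", "inplane_mm", "contrast")
  if (!is.data.frame(protocols) || !all(need %in% names(protocols)))
    stop("'protocols' must be a data.frame with columns ",
         paste(need, collapse = ", "))
  timepoints <- as.integer(timepoints)
  subjects <- as.integer(subjects)
  if (is.na(timepoints) || timepoints < 1L) stop("'timepoints' must be >= 1")
  if (is.na(subjects) || subjects < 1L) stop("'subjects' must be >= 1")
  structure(list(scanners = scanners, protocols = protocols,
                 timepoints = timepoints, subjects = subjects),
            class = "study_layout")
}

#' @rdname study_layout
#' @export
layout_phantom <- function() {
  study_layout(
    scanners = c("scanner1", "scanner2", "scanner3"),
    protocols = data.frame(
      name = paste0("P", 1:6),
      mA = c(100, 100, 200, 200, 300, 300),
      thickness_mm = c(2, 5, 2, 5, 2, 5),
      inplane_mm = rep(0.86, 6),
      contrast = FALSE),
    timepoints = 2L, subjects = 1L)
}

# Scanner 3 reconstructs at 2.5/5 mm with a 0.9653 mm in-plane grid; the
# in-plane/thickness columns above hold for scanners 1-2 and are overridden
# per scanner when phantom volumes are generated.
scanner3_protocol <- function(protocol) {
  protocol$inplane_mm <- 0.9653
  if (protocol$thickness_mm == 2) protocol$thickness_mm <- 2.5
  protocol
}

#' @rdname study_layout
#' @export
layout_clinical <- function(subjects = 104L) {
  study_layout(
    scanners = "scanner2",
    protocols = data.frame(
      name = c("BLDCT5", "WBCECT2", "NCCTT2"),
      mA = c(150, 150, 300),
      thickness_mm = c(5, 2, 2),
      inplane_mm = c(1.17, 1.17, 0.87),
      contrast = c(TRUE, TRUE, FALSE)),
    timepoints = 1L, subjects = subjects)
}

#' @rdname study_layout
#' @export
layout_rider <- function(subjects = 32L) {
  study_layout(
    scanners = "scanner_rider",
    protocols = data.frame(name = "RIDER", mA = 350, thickness_mm = 1.25,
                           inplane_mm = 0.66, contrast = FALSE),
    timepoints = 2L, subjects = subjects)
}

# Deterministic per-slot seed: splits one user seed into independent streams
# keyed by slot labels, so any (scanner, protocol, timepoint, feature) slot
# can be regenerated on its own. Kept below 2^31 - 1.
slot_seed <- function(seed, ...) {
  key <- paste(c(...), collapse = "|")
  h <- 0
  for (v in utf8ToInt(key)) h <- (h * 131 + v) %% 2147483629
  as.integer((as.numeric(seed) %% 2147483629 * 7919 + h) %% 2147483629) + 1L
}

#' Simulate a long-format feature table with known ICC structure
#'
#' For every feature, cell values follow the two-way model documented in
#' [variance_components()], over rows = subjects and columns = all
#' scanner x protocol x timepoint combinations of the layout. The same seed
#' yields a byte-identical table; the table is complete (no missing cells).
#'
#' @param layout a [study_layout()] with >= 2 subjects and >= 2 columns.
#' @param components a single [variance_components()] (recycled) or a list of
#'   length `n_features`.
#' @param n_features number of features to simulate (>= 1).
#' @param seed integer seed.
#' @param feature_ids optional character vector of feature names.
#' @param mu per-feature grand mean (scalar or length `n_features`).
#' @return a `data.frame` with columns
#'   `subject, scanner, protocol, timepoint, feature, value`.
#' @export
simulate_feature_table <- function(layout, components, n_features, seed = 1L,
                                   feature_ids = NULL, mu = 0) {
  if (!inherits(layout, "study_layout")) stop("'layout' must be a study_layout")
  n_features <- as.integer(n_features)
  if (is.na(n_features) || n_features < 1L)
    stop("'n_features' must be a positive count")
  cols <- expand.grid(timepoint = paste0("T", seq_len(layout$timepoints)),
                      protocol = layout$protocols$name,
                      scanner = layout$scanners,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  k <- nrow(cols)
  n <- layout$subjects
  if (n < 2L) stop("'subjects' must be >= 2 to estimate consistency")
  if (k < 2L) stop("layout must provide >= 2 measurement columns")
  if (inherits(components, "variance_components"))
    components <- rep(list(components), n_features)
  if (length(components) != n_features)
    stop("'components' must have one entry per feature")
  if (is.null(feature_ids))
    feature_ids <- sprintf("f%04d", seq_len(n_features))
  mu <- rep_len(mu, n_features)
  subjects <- sprintf("S%03d", seq_len(n))
  vals <- matrix(0, n * k, n_features)
  for (f in seq_len(n_features)) {
    vc <- components[[f]]
    if (!inherits(vc, "variance_components"))
      stop("components[[", f, "]] is not a variance_components object")
    set.seed(slot_seed(seed, "feature", feature_ids[f]))
    # scale standard normals so every component consumes the same number
    # of draws regardless of its variance (stream-aligned across settings)
    s <- sqrt(vc$subject_var) * rnorm(n)
    r <- sqrt(vc$rater_var) * rnorm(k)
    e <- matrix(sqrt(vc$residual_var) * rnorm(n * k), n, k)
    vals[, f] <- as.vector(outer(s, r, "+") + e) + mu[f]
  }
  out <- data.frame(
    subject = rep(rep(subjects, k), n_features),
    scanner = rep(rep(cols$scanner, each = n), n_features),
    protocol = rep(rep(cols$protocol, each = n), n_features),
    timepoint = rep(rep(cols$timepoint, each = n), n_features),
    feature = rep(feature_ids, each = n * k),
    value = as.vector(vals),
    stringsAsFactors = FALSE)
  out
}

#' Specification of the synthetic image-quality phantom
#'
#' A homogeneous sphere (the fillable insert) centered in a uniform
#' background, with a target-to-background intensity ratio of 4:1 and
#' additive Gaussian noise whose standard deviation follows the first-order
#' CT quantum-noise law \eqn{\sigma = \sigma_{ref}\sqrt{ref\_mAs\,mm /
#' (mA \cdot thickness)}}. Edges are softened by 3x-per-axis supersampled
#' sphere-membership averaging (partial volume).
#'
#' @param sphere_diameter_mm insert diameter (default 37 mm).
#' @param target_background_ratio sphere:background mean intensity ratio.
#' @param background_level background mean intensity.
#' @param noise_reference noise standard deviation at the reference
#'   exposure product.
#' @param reference_mAs_mm reference mA x slice-thickness product.
#' @param fov_mm physical field of view per axis (sphere must fit inside).
#' @param interior_length_mm phantom interior length (metadata only).
#' @export
phantom_spec <- function(sphere_diameter_mm = 37,
                         target_background_ratio = 4,
                         background_level = 100,
                         noise_reference = 10,
                         reference_mAs_mm = 1500,
                         fov_mm = c(64, 64, 64),
                         interior_length_mm = 180) {
  stopifnot(sphere_diameter_mm > 0, target_background_ratio > 0,
            background_level > 0, noise_reference >= 0,
            reference_mAs_mm > 0, length(fov_mm) == 3L, all(fov_mm > 0))
  structure(list(sphere_diameter_mm = sphere_diameter_mm,
                 target_background_ratio = target_background_ratio,
                 background_level = background_level,
                 noise_reference = noise_reference,
                 reference_mAs_mm = reference_mAs_mm,
                 fov_mm = fov_mm,
                 interior_length_mm = interior_length_mm),
            class = "phantom_spec")
}

#' Noise level implied by a protocol
#' @param spec a [phantom_spec()].
#' @param protocol one row of a layout's protocol table.
#' @export
protocol_noise_sd <- function(spec, protocol) {
  spec$noise_reference *
    sqrt(spec$reference_mAs_mm / (protocol$mA * protocol$thickness_mm))
}

#' Generate one synthetic phantom scan
#'
#' Returns the noisy intensity volume and the exact voxelized sphere mask
#' (voxel centers inside the sphere) on the protocol's grid. Two calls with
#' the same seed are identical; different timepoints passed different seeds
#' differ only in the noise realization.
#'
#' @param spec a [phantom_spec()].
#' @param protocol one row of a protocol table (`mA`, `thickness_mm`,
#'   `inplane_mm`).
#' @param timepoint label entering the per-slot random stream.
#' @param seed integer master seed.
#' @param scanner optional scanner label entering the per-slot stream.
#' @return `list(volume = image_volume, mask = roi_mask)`.
#' @export
generate_phantom_volume <- function(spec, protocol, timepoint = "T1",
                                    seed = 1L, scanner = "scanner1") {
  spacing <- c(protocol$inplane_mm, protocol$inplane_mm, protocol$thickness_mm)
  if (any(spacing <= 0)) stop("protocol voxel sizes must be > 0")
  if (spec$sphere_diameter_mm > min(spec$fov_mm))
    stop("sphere (", spec$sphere_diameter_mm,
         " mm) does not fit inside the field of view")
  dims <- pmax(2L, as.integer(round(spec$fov_mm / spacing)))
  r <- spec$sphere_diameter_mm / 2
  center <- (dims - 1) * spacing / 2
  ax <- lapply(1:3, function(a) (seq_len(dims[a]) - 1) * spacing[a] - center[a])
  # squared distance field, built separably
  d2 <- outer(outer(ax[[1]] ^ 2, ax[[2]] ^ 2, "+"), ax[[3]] ^ 2, "+")
  # partial-volume fraction: 3x supersampling per axis (27 subsamples/voxel)
  off <- c(-1, 0, 1) / 3
  frac <- array(0, dims)
  for (ox in off) for (oy in off) for (oz in off) {
    s2 <- outer(outer((ax[[1]] + ox * spacing[1]) ^ 2,
                      (ax[[2]] + oy * spacing[2]) ^ 2, "+"),
                (ax[[3]] + oz * spacing[3]) ^ 2, "+")
    frac <- frac + (s2 <= r ^ 2)
  }
  frac <- frac / 27
  bg <- spec$background_level
  signal <- bg * (1 + (spec$target_background_ratio - 1) * frac)
  sd_noise <- protocol_noise_sd(spec, protocol)
  if (sd_noise > 0) {
    set.seed(slot_seed(seed, scanner, protocol$name, timepoint))
    signal <- signal + array(rnorm(prod(dims), 0, sd_noise), dims)
  }
  mask <- roi_mask(d2 <= r ^ 2, spacing)
  list(volume = image_volume(signal, spacing), mask = mask)
}

# Construct an n x k matrix whose SAMPLE consistency ICC equals `rho`
# exactly: row effects with unit-norm contrasts and a doubly-centered
# residual matrix are scaled to the mean squares that solve
# (MS_R - MS_E)/(MS_R + (k-1) MS_E) = rho. Random rater offsets and a grand
# mean are added; neither enters the consistency coefficient.
exact_icc_matrix <- function(n, k, rho, seed, mu = 0, rater_sd = 0.5) {
  stopifnot(n >= 3, k >= 2, rho > -1 / (k - 1), rho < 1)
  set.seed(seed)
  s <- rnorm(n)
  s <- s - mean(s)
  s <- s / sqrt(sum(s ^ 2))
  E <- matrix(rnorm(n * k), n, k)
  E <- sweep(E, 1, rowMeans(E))
  E <- sweep(E, 2, colMeans(E))
  E <- E / sqrt(sum(E ^ 2)) * sqrt((n - 1) * (k - 1))  # MS_E = 1
  ms_r <- (1 + (k - 1) * rho) / (1 - rho)
  a <- sqrt(ms_r * (n - 1) / k)
  r <- rnorm(k, 0, rater_sd)
  mu + a * tcrossprod(s, rep(1, k)) + tcrossprod(rep(1, n), r) + E
}

# Long-format table whose per-feature sample ICC is exactly the designed
# value. Used by the clinical / rider fixtures so that classification
# recovery is deterministic.
exact_feature_table <- function(layout, icc_targets, seed, feature_ids) {
  cols <- expand.grid(timepoint = paste0("T", seq_len(layout$timepoints)),
                      protocol = layout$protocols$name,
                      scanner = layout$scanners,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  k <- nrow(cols)
  n <- layout$subjects
  nf <- length(icc_targets)
  subjects <- sprintf("S%03d", seq_len(n))
  vals <- matrix(0, n * k, nf)
  for (f in seq_len(nf))
    vals[, f] <- as.vector(exact_icc_matrix(
      n, k, icc_targets[f], slot_seed(seed, "feature", feature_ids[f])))
  data.frame(
    subject = rep(rep(subjects, k), nf),
    scanner = rep(rep(cols$scanner, each = n), nf),
    protocol = rep(rep(cols$protocol, each = n), nf),
    timepoint = rep(rep(cols$timepoint, each = n), nf),
    feature = rep(feature_ids, each = n * k),
    value = as.vector(vals),
    stringsAsFactors = FALSE)
}

#' Build a complete synthetic study fixture
#'
#' `"phantom"` yields the 36 labeled (scanner, protocol, timepoint) volume +
#' mask pairs of the image-quality phantom design. `"clinical"` yields a
#' long-format feature table for 104 subjects x 3 clinical protocols with a
#' per-subject tumor-volume covariate (cm^3) and a designated 10% of features
#' constructed as monotone functions of that volume, so the collinearity
#' filter has true positives with known identity. `"rider"` yields a
#' test-retest table for 32 subjects x 2 scans. Feature tables carry a
#' `design` attribute with the per-feature truth (tier, true ICC, proxy
#' flag). Unlike the stochastic [simulate_feature_table()], fixture tables
#' are built so each feature's sample ICC equals its designed tier value
#' exactly (row effects and doubly-centered residuals scaled to the target
#' mean squares), making tier recovery deterministic.
#'
#' @param preset one of `"phantom"`, `"clinical"`, `"rider"`.
#' @param seed integer master seed.
#' @param n_features number of simulated features for the table presets
#'   (default the full 1080-feature roster, named canonically).
#' @param spec a [phantom_spec()] for the phantom preset.
#' @param dir optional directory: phantom volumes/masks are written as NRRD
#'   with a JSON manifest; tables as CSV.
#' @param tiers named numeric vector of designed true ICC tiers.
#' @param tier_prop tier mixing proportions (same order), summing to 1.
#' @return for `"phantom"` a list of 36 slots; otherwise a feature table
#'   `data.frame` with attributes `design` and `gtv_cm3`.
#' @export
make_study_fixture <- function(preset = c("phantom", "clinical", "rider"),
                               seed = 1L, n_features = NULL, spec = phantom_spec(),
                               dir = NULL,
                               tiers = c(good = 0.95, moderate = 0.85, poor = 0.5),
                               tier_prop = c(good = 0.2, moderate = 0.3, poor = 0.5)) {
  preset <- tryCatch(match.arg(preset), error = function(e)
    stop("unknown preset; valid presets: phantom, clinical, rider"))
  if (preset == "phantom") {
    layout <- layout_phantom()
    slots <- list()
    for (sc in layout$scanners) for (p in seq_len(nrow(layout$protocols))) {
      proto <- layout$protocols[p, ]
      if (sc == "scanner3") proto <- scanner3_protocol(proto)
      for (tp in paste0("T", seq_len(layout$timepoints))) {
        pair <- generate_phantom_volume(spec, proto, timepoint = tp,
                                        seed = seed, scanner = sc)
        slots[[length(slots) + 1L]] <- list(
          scanner = sc, protocol = proto$name, timepoint = tp,
          volume = pair$volume, mask = pair$mask)
      }
    }
    if (!is.null(dir)) write_fixture_dir(slots, dir, seed)
    return(structure(slots, class = "study_fixture", preset = "phantom",
                     seed = seed))
  }
  layout <- if (preset == "clinical") layout_clinical() else layout_rider()
  if (is.null(n_features)) {
    feature_ids <- feature_name_roster()
    n_features <- length(feature_ids)
  } else {
    feature_ids <- sprintf("f%04d", seq_len(n_features))
  }
  stopifnot(abs(sum(tier_prop) - 1) < 1e-9, all(names(tiers) == names(tier_prop)))
  # deterministic tier assignment by feature index (same across presets)
  cuts <- floor(cumsum(tier_prop) * n_features)
  tier <- rep(names(tiers), times = diff(c(0, cuts)))
  tier <- rep_len(tier, n_features)
  # sample ICC equals the tier value exactly, so classification recovery
  # is deterministic by construction
  tab <- exact_feature_table(layout, unname(tiers[tier]), seed, feature_ids)
  design <- data.frame(feature = feature_ids, tier = tier,
                       true_icc = tiers[tier],
                       volume_proxy = FALSE, stringsAsFactors = FALSE)
  gtv <- NULL
  if (preset == "clinical") {
    set.seed(slot_seed(seed, "gtv"))
    # lognormal GTV, median ~92 cm^3, clamped to a plausible 10-500 range
    gtv <- pmin(pmax(rlnorm(layout$subjects, log(92), 0.7), 10), 500)
    names(gtv) <- sprintf("S%03d", seq_len(layout$subjects))
    proxy <- seq_len(n_features) %% 10L == 0L  # designated 10%
    design$volume_proxy <- proxy
    set.seed(slot_seed(seed, "proxy-noise"))
    nk <- layout$subjects * nrow(layout$protocols) * layout$timepoints
    for (f in which(proxy)) {
      rows_f <- (f - 1L) * nk + seq_len(nk)  # features are stored in blocks
      b <- 0.5 + (f %% 3L) * 0.5             # exponents 0.5, 1.0, 1.5
      base <- gtv[tab$subject[rows_f]] ^ b
      tab$value[rows_f] <- base * (1 + rnorm(nk, 0, 0.01))
      design$tier[f] <- "proxy"
      design$true_icc[f] <- NA_real_
    }
  }
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(tab, file.path(dir, paste0(preset, "_features.csv")),
                     row.names = FALSE)
    if (!is.null(gtv))
      utils::write.csv(data.frame(subject = names(gtv), gtv_cm3 = gtv),
                       file.path(dir, "gtv.csv"), row.names = FALSE)
  }
  structure(tab, design = design, gtv_cm3 = gtv, preset = preset, seed = seed)
}

# Write phantom fixture slots as NRRD pairs plus a JSON manifest.
write_fixture_dir <- function(slots, dir, seed) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- lapply(slots, function(s) {
    stem <- sprintf("%s_%s_%s", s$scanner, s$protocol, s$timepoint)
    write_nrrd(s$volume, file.path(dir, paste0(stem, "_image.nrrd")))
    write_nrrd(s$mask, file.path(dir, paste0(stem, "_mask.nrrd")))
    list(scanner = s$scanner, protocol = s$protocol, timepoint = s$timepoint,
         image = paste0(stem, "_image.nrrd"), mask = paste0(stem, "_mask.nrrd"))
  })
  jsonlite::write_json(list(seed = seed, slots = manifest),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}
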