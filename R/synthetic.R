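#' Gaussian band specification
#'
#' Describes one vibrational/overtone band of the synthetic spectrum model:
#' a Gaussian line with a physical full width at half maximum, a base
#' amplitude, and multiplicative modifiers for tumour class and organ.
#' These modifiers are free generator parameters that emulate the *kind* of
#' class and organ contrasts seen in gastrointestinal tissue spectra
#' (e.g. a reduced lipid carbonyl band in tumours); they are not estimates
#' of any clinical dataset.
#'
#' @param center band centre, in the units of the modality axis (cm^-1 for
#'   MIR, nm for NIR).
#' @param width full width at half maximum, same units; must be > 0.
#' @param amplitude base peak amplitude (arbitrary intensity), >= 0.
#' @param class_effect multiplicative amplitude factor applied for tumour
#'   ("T") rows; > 0.
#' @param organ_effects named numeric vector of per-organ multiplicative
#'   factors (missing organs default to 1); all > 0.
#' @param class_effect_by_organ optional named numeric vector overriding
#'   `class_effect` for specific organs (organ-specific class contrast).
#' @param name optional label used in error messages.
#'
#' @return An object of class `band_spec`.
#' @export
band_spec <- function(center, width, amplitude, class_effect = 1,
                      organ_effects = NULL, class_effect_by_organ = NULL,
                      name = NULL) {
  if (width <= 0) stop("band width must be > 0")
  if (amplitude < 0) stop("band amplitude must be >= 0")
  if (class_effect <= 0) stop("class_effect must be > 0")
  if (!is.null(organ_effects) && any(organ_effects <= 0))
    stop("organ effect factors must be > 0")
  if (!is.null(class_effect_by_organ) && any(class_effect_by_organ <= 0))
    stop("class effect factors must be > 0")
  structure(
    list(center = center, width = width, amplitude = amplitude,
         class_effect = class_effect,
         organ_effects = organ_effects,
         class_effect_by_organ = class_effect_by_organ,
         name = if (is.null(name)) sprintf("band@%g", center) else name),
    class = "band_spec"
  )
}

band_amplitude <- function(band, organ, class) {
  amp <- band$amplitude
  if (!is.null(band$organ_effects) && organ %in% names(band$organ_effects))
    amp <- amp * band$organ_effects[[organ]]
  if (class == "T") {
    ce <- band$class_effect
    if (!is.null(band$class_effect_by_organ) &&
        organ %in% names(band$class_effect_by_organ))
      ce <- band$class_effect_by_organ[[organ]]
    amp <- amp * ce
  }
  amp
}

#' Evaluate one Gaussian band on a channel grid
#'
#' The line shape is Gaussian parameterised by its full width at half
#' maximum: `amplitude * exp(-log(2) * (2 * (x - center) / width)^2)`, so the
#' value at `center +/- width/2` is exactly half the amplitude.
#'
#' @param band a [band_spec()].
#' @param axis strictly monotone channel grid.
#' @param amplitude peak amplitude; defaults to the band's base amplitude.
#' @return numeric vector, same length as `axis`.
#' @export
band_profile <- function(band, axis, amplitude = band$amplitude) {
  d <- diff(axis)
  if (length(d) && !(all(d > 0) || all(d < 0)))
    stop("axis must be strictly monotone")
  if (band$center < min(axis) || band$center > max(axis))
    stop("band '", band$name, "' centre ", band$center,
         " lies outside the axis range [", min(axis), ", ", max(axis), "]")
  amplitude * exp(-log(2) * (2 * (axis - band$center) / band$width)^2)
}

#' Generate one synthetic spectrum
#'
#' Deterministic signal model:
#' `scatter * (exp(patient_effect) * sum of band profiles + baseline) + noise`,
#' where the baseline is linear across the axis
#' (`baseline[1] + baseline[2] * u`, `u` the 0..1 normalised axis position)
#' and the additive noise is i.i.d. Gaussian drawn from the current RNG
#' state when `noise_sd > 0`.
#'
#' @param bands list of [band_spec()] objects.
#' @param organ organ label used to resolve organ/class effects.
#' @param class `"N"` or `"T"`.
#' @param axis channel grid (same units as the band centres).
#' @param patient_effect patient-level log-amplitude random effect (scalar).
#' @param baseline length-2 numeric `(intercept, slope)` of the linear
#'   baseline drift.
#' @param scatter multiplicative scatter factor (emulates variable probe
#'   contact pressure), > 0.
#' @param noise_sd standard deviation of the additive noise.
#' @param band_scales optional per-band multiplicative factors (length of
#'   `bands`) emulating position-level compositional variability; default 1.
#' @return numeric intensity vector, same length as `axis`.
#' @export
generate_spectrum <- function(bands, organ, class, axis,
                              patient_effect = 0, baseline = c(0, 0),
                              scatter = 1, noise_sd = 0,
                              band_scales = NULL) {
  if (is.null(band_scales)) band_scales <- rep(1, length(bands))
  if (length(band_scales) != length(bands))
    stop("band_scales must have one factor per band")
  signal <- numeric(length(axis))
  for (i in seq_along(bands))
    signal <- signal + band_profile(bands[[i]], axis,
                                    band_scales[i] *
                                      band_amplitude(bands[[i]], organ, class))
  u <- if (length(axis) > 1) (axis - min(axis)) / diff(range(axis)) else 0
  base <- baseline[1] + baseline[2] * u
  out <- scatter * (exp(patient_effect) * signal + base)
  if (noise_sd > 0) out <- out + stats::rnorm(length(axis), 0, noise_sd)
  out
}

#' Synthetic cohort configuration
#'
#' Defines the design of a paired MIR/NIR cohort: per-organ patient counts
#' and class balance, the magnitudes of the patient-level random effect and
#' of the measurement artifacts, the number of raw replicates per position,
#' and the root seed. The default design mirrors a three-organ
#' gastrointestinal study: 52 colon positions (27 normal, 25 tumour) from 10
#' patients, 52 stomach positions (32N, 20T) from 12 patients, and 21 rectum
#' positions (9N, 12T) from 6 patients.
#'
#' @param organs named list; each element a list with `patients`, `n_normal`,
#'   `n_tumour`.
#' @param patient_effect_sd s.d. of the per-patient log-amplitude random
#'   effect (shared across all of that patient's positions).
#' @param baseline_drift_amplitude s.d. of the linear baseline coefficients
#'   drawn per replicate.
#' @param scatter_slope_sd s.d. of the log multiplicative scatter factor
#'   drawn per replicate (contact-pressure variation).
#' @param noise_sd additive Gaussian noise s.d. per channel.
#' @param band_jitter_sd s.d. of the per-position, per-band log-amplitude
#'   jitter (compositional heterogeneity between measurement positions;
#'   drawn independently per modality, since the two instruments probe
#'   different tissue volumes).
#' @param replicate_count raw replicates per position and modality.
#' @param seed root seed; fully determines the cohort.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(organs = list(
                            colon   = list(patients = 10, n_normal = 27, n_tumour = 25),
                            stomach = list(patients = 12, n_normal = 32, n_tumour = 20),
                            rectum  = list(patients = 6,  n_normal = 9,  n_tumour = 12)),
                          patient_effect_sd = 0.15,
                          baseline_drift_amplitude = 0.50,
                          scatter_slope_sd = 0.30,
                          noise_sd = 0.08,
                          band_jitter_sd = 0.10,
                          replicate_count = 3,
                          seed = 1) {
  for (nm in names(organs)) {
    o <- organs[[nm]]
    if (o$patients < 1 || o$n_normal + o$n_tumour < 1)
      stop("organ '", nm, "': counts must be >= 1")
  }
  if (patient_effect_sd < 0 || baseline_drift_amplitude < 0 ||
      scatter_slope_sd < 0 || noise_sd < 0 || band_jitter_sd < 0)
    stop("all s.d. parameters must be >= 0")
  if (replicate_count < 1) stop("replicate_count must be >= 1")
  structure(
    list(organs = organs, patient_effect_sd = patient_effect_sd,
         baseline_drift_amplitude = baseline_drift_amplitude,
         scatter_slope_sd = scatter_slope_sd, noise_sd = noise_sd,
         band_jitter_sd = band_jitter_sd,
         replicate_count = replicate_count, seed = as.integer(seed)),
    class = "cohort_config"
  )
}

## Deterministic child-seed derivation: each (stream, index...) tuple gets
## its own seed, so enlarging one organ never reshuffles the draws of
## another. Linear-congruential mix kept below 2^31.
seed_child <- function(root, ...) {
  ix <- c(...)
  h <- as.double(root %% 2147483647)
  for (v in ix) h <- (h * 48271 + as.double(v) + 11) %% 2147483647
  as.integer(h)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Evenly interleave the two class labels so every patient sees both
## classes where possible; deterministic, independent of the seed.
interleave_labels <- function(n_normal, n_tumour) {
  keys <- c(seq_len(n_normal) / (n_normal + 1),
            seq_len(n_tumour) / (n_tumour + 1))
  labs <- c(rep("N", n_normal), rep("T", n_tumour))
  labs[order(keys, labs)]
}

#' Default MIR band set
#'
#' Fingerprint-region bands at the positions characteristic of
#' gastrointestinal tissue: lipid carbonyl (1742 cm^-1), amide I/II
#' (1642/1550), lipid CH2 bending (1458), phosphate PO2- (1240, 1083),
#' protein C-OH (1155) and the glycogen complex (1125, 1080, 1043, 1040).
#' Organ factors make rectal spectra lipid- and phosphate-rich and colon
#' spectra glycogen-rich; class factors raise amide and colon-glycogen
#' bands and deplete lipid and stomach-glycogen bands in tumours.
#'
#' @param organ_strength exponent scaling the organ heterogeneity
#'   (0 = organs exchangeable, 1 = default).
#' @param class_strength exponent scaling all class contrasts
#'   (0 = classes exchangeable, 1 = default).
#' @param organ_specific_classes keep the organ-specific class contrasts
#'   (e.g. glycogen up in colon tumours but down in stomach tumours);
#'   if `FALSE` only the scalar class factors remain.
#' @return list of [band_spec()] objects.
#' @export
default_mir_bands <- function(organ_strength = 1, class_strength = 1,
                              organ_specific_classes = TRUE) {
  pw <- function(x, s) x^s
  oe <- function(...) {
    v <- c(...)
    if (organ_strength == 0) NULL else pw(v, organ_strength)
  }
  ce <- function(x) pw(x, class_strength)
  cbo <- function(...) {
    if (!organ_specific_classes) return(NULL)
    pw(c(...), class_strength)
  }
  list(
    band_spec(1742, 26, 0.50, class_effect = ce(0.89),
              organ_effects = oe(rectum = 1.5), name = "lipid C=O"),
    band_spec(1642, 42, 1.00, class_effect = ce(1.07), name = "amide I"),
    band_spec(1550, 34, 0.80, class_effect = ce(1.06), name = "amide II"),
    band_spec(1458, 26, 0.45, class_effect = ce(0.95),
              organ_effects = oe(rectum = 1.4), name = "lipid CH2"),
    band_spec(1240, 30, 0.40, class_effect = ce(1.05),
              organ_effects = oe(rectum = 1.3), name = "PO2- asym"),
    band_spec(1155, 24, 0.35, class_effect = ce(0.95),
              organ_effects = oe(rectum = 1.25), name = "C-OH protein"),
    band_spec(1125, 22, 0.35, class_effect = ce(1.00),
              organ_effects = oe(stomach = 1.2),
              class_effect_by_organ = cbo(stomach = 0.90), name = "glycogen 1125"),
    band_spec(1083, 20, 0.40, class_effect = ce(1.06),
              organ_effects = oe(rectum = 1.3), name = "PO2- sym"),
    band_spec(1080, 22, 0.30, class_effect = ce(1.00),
              organ_effects = oe(stomach = 1.2),
              class_effect_by_organ = cbo(stomach = 0.90), name = "glycogen 1080"),
    band_spec(1043, 20, 0.50, class_effect = ce(1.05),
              organ_effects = oe(colon = 1.3),
              class_effect_by_organ = cbo(colon = 1.10, stomach = 0.90),
              name = "glycogen 1043"),
    band_spec(1040, 22, 0.30, class_effect = ce(1.00),
              organ_effects = oe(stomach = 1.2),
              class_effect_by_organ = cbo(stomach = 0.90), name = "glycogen 1040")
  )
}

#' Default NIR band set
#'
#' Broad overtone/combination bands: CH stretching second overtone
#' (~1100-1200 nm), OH/NH first overtone combinations (~1300-1420 nm) and
#' CH combination bands (~1400-1600 nm), plus a short-wavelength shoulder.
#'
#' @inheritParams default_mir_bands
#' @return list of [band_spec()] objects.
#' @export
default_nir_bands <- function(organ_strength = 1, class_strength = 1,
                              organ_specific_classes = TRUE) {
  pw <- function(x, s) x^s
  oe <- function(...) {
    v <- c(...)
    if (organ_strength == 0) NULL else pw(v, organ_strength)
  }
  ce <- function(x) pw(x, class_strength)
  cbo <- function(...) {
    if (!organ_specific_classes) return(NULL)
    pw(c(...), class_strength)
  }
  list(
    band_spec(955, 70, 0.40, class_effect = ce(0.92),
              organ_effects = oe(rectum = 1.15), name = "OH 2nd overtone"),
    band_spec(1150, 85, 0.60, class_effect = ce(1.10),
              organ_effects = oe(rectum = 1.2),
              class_effect_by_organ = cbo(rectum = 1.14), name = "CH 2nd overtone"),
    band_spec(1360, 95, 0.80, class_effect = ce(0.91),
              organ_effects = oe(stomach = 1.15),
              class_effect_by_organ = cbo(stomach = 0.88), name = "OH/NH 1st overtone"),
    band_spec(1500, 120, 0.90, class_effect = ce(1.09),
              organ_effects = oe(colon = 1.15),
              class_effect_by_organ = cbo(colon = 1.12), name = "CH combination")
  )
}

#' Generate a paired synthetic MIR/NIR cohort
#'
#' Every position is measured by both modalities (`replicate_count` raw
#' replicates each); both blocks share position ids, patient ids, organs and
#' class labels. All randomness derives from `config$seed` through
#' per-(organ, patient/position, replicate, modality) child streams, so the
#' output is bit-identical across runs and stable under cohort enlargement.
#'
#' @param config a [cohort_config()].
#' @param mir_bands,nir_bands band lists, see [default_mir_bands()].
#' @return list with elements `mir` and `nir` (each a [spectra_block()]) and
#'   `config`.
#' @export
generate_cohort <- function(config = cohort_config(),
                            mir_bands = default_mir_bands(),
                            nir_bands = default_nir_bands()) {
  stopifnot(inherits(config, "cohort_config"))
  axes <- list(mir = mir_axis(), nir = nir_axis())
  bands <- list(mir = mir_bands, nir = nir_bands)
  blocks <- list(mir = NULL, nir = NULL)
  meta <- NULL
  rows <- list(mir = list(), nir = list())

  organ_names <- names(config$organs)
  for (oi in seq_along(organ_names)) {
    organ <- organ_names[oi]
    o <- config$organs[[organ]]
    n_pos <- o$n_normal + o$n_tumour
    labels <- interleave_labels(o$n_normal, o$n_tumour)
    patient_of <- ((seq_len(n_pos) - 1L) %% o$patients) + 1L
    pat_eff <- vapply(seq_len(o$patients), function(k)
      with_seed(seed_child(config$seed, 1L, oi, k),
                stats::rnorm(1, 0, config$patient_effect_sd)),
      numeric(1))
    for (p in seq_len(n_pos)) {
      pos_id <- sprintf("%s_%03d", organ, p)
      pat_id <- sprintf("%s_P%02d", organ, patient_of[p])
      jitter <- lapply(1:2, function(mi)
        with_seed(seed_child(config$seed, 3L, oi, p, mi),
                  exp(stats::rnorm(length(bands[[c("mir", "nir")[mi]]]),
                                   0, config$band_jitter_sd))))
      for (r in seq_len(config$replicate_count)) {
        for (mi in 1:2) {
          mod <- c("mir", "nir")[mi]
          sp <- with_seed(seed_child(config$seed, 2L, oi, p, r, mi), {
            base <- stats::rnorm(2, 0, config$baseline_drift_amplitude)
            sc <- exp(stats::rnorm(1, 0, config$scatter_slope_sd))
            generate_spectrum(bands[[mod]], organ, labels[p], axes[[mod]],
                              patient_effect = pat_eff[patient_of[p]],
                              baseline = base, scatter = sc,
                              noise_sd = config$noise_sd,
                              band_scales = jitter[[mi]])
          })
          rows[[mod]][[length(rows[[mod]]) + 1L]] <- sp
        }
        meta <- rbind(meta, data.frame(
          position = pos_id, patient = pat_id, organ = organ,
          class = labels[p], replicate = r, stringsAsFactors = FALSE))
      }
    }
  }
  for (mod in c("mir", "nir")) {
    m <- do.call(rbind, rows[[mod]])
    blocks[[mod]] <- spectra_block(m, axes[[mod]], mod, meta)
  }
  structure(list(mir = blocks$mir, nir = blocks$nir, config = config),
            class = "spectra_cohort")
}

#' @export
print.spectra_cohort <- function(x, ...) {
  cat("<spectra_cohort> paired MIR/NIR, seed", x$config$seed, "\n")
  print(x$mir)
  invisible(x)
}

#' Generator preset: complementary class information across modalities
#'
#' Band sets in which the tumour contrast is carried by *different* bands in
#' the two modalities, each modality alone only moderately informative, so
#' that concatenating the blocks recovers a synergy gain. Effect sizes and
#' noise are fixed design choices sized so that single-modality leave-one-out
#' accuracy falls in the 70-85% band on the default cohort design.
#'
#' @param seed root seed stored in the returned config.
#' @return list with `config`, `mir_bands`, `nir_bands`, ready for
#'   [generate_cohort()].
#' @export
preset_complementary <- function(seed = 1) {
  mir <- default_mir_bands(class_strength = 0, organ_specific_classes = FALSE)
  ## MIR carries the tumour contrast for colon and rectum positions only
  mir[[2]]$class_effect_by_organ <- c(colon = 1.68, rectum = 1.68)   # amide I
  mir[[3]]$class_effect_by_organ <- c(colon = 1.60, rectum = 1.60)   # amide II
  mir[[10]]$class_effect_by_organ <- c(colon = 1.88, rectum = 1.88)  # glycogen 1043
  nir <- default_nir_bands(class_strength = 0, organ_specific_classes = FALSE)
  ## NIR carries it for stomach and rectum positions only
  nir[[3]]$class_effect_by_organ <- c(stomach = 0.76, rectum = 0.76)
  nir[[4]]$class_effect_by_organ <- c(stomach = 1.28, rectum = 1.28)
  cfg <- cohort_config(seed = seed)
  list(config = cfg, mir_bands = mir, nir_bands = nir)
}

#' Generator preset: strong organ-specific class structure
#'
#' Keeps the default organ baselines and strengthens the organ-specific
#' tumour contrasts so that they point in *conflicting directions* across
#' organs (e.g. glycogen up in colon tumours, down in stomach tumours).
#' One joint linear classifier cannot serve all organs at once, so
#' per-organ ("local") models hold a structural advantage over the joint
#' ("global") model.
#'
#' @param seed root seed stored in the returned config.
#' @return list with `config`, `mir_bands`, `nir_bands`.
#' @export
preset_organ_heterogeneous <- function(seed = 1) {
  mir <- default_mir_bands()
  mir[[2]]$class_effect_by_organ <- c(colon = 1.25, stomach = 0.82, rectum = 1.30)  # amide I
  mir[[3]]$class_effect_by_organ <- c(colon = 1.20, stomach = 0.85, rectum = 1.25)  # amide II
  mir[[10]]$class_effect_by_organ <- c(colon = 1.40, stomach = 0.70, rectum = 1.10) # glycogen 1043
  nir <- default_nir_bands()
  nir[[2]]$class_effect_by_organ <- c(colon = 1.18, stomach = 0.85, rectum = 1.18)
  nir[[3]]$class_effect_by_organ <- c(colon = 0.85, stomach = 1.18, rectum = 0.88)
  nir[[4]]$class_effect_by_organ <- c(colon = 1.16, stomach = 0.86, rectum = 1.16)
  list(config = cohort_config(seed = seed), mir_bands = mir, nir_bands = nir)
}

#' Generator preset: exchangeable organs
#'
#' Organ effects and organ-specific class contrasts switched off, so the
#' three organs share one spectral distribution and per-organ models have no
#' structural advantage over the joint model.
#'
#' @param seed root seed stored in the returned config.
#' @return list with `config`, `mir_bands`, `nir_bands`.
#' @export
preset_organ_null <- function(seed = 1) {
  list(config = cohort_config(seed = seed),
       mir_bands = default_mir_bands(organ_strength = 0,
                                     organ_specific_classes = FALSE),
       nir_bands = default_nir_bands(organ_strength = 0,
                                     organ_specific_classes = FALSE))
}
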