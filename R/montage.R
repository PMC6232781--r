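# 32-channel 10-20 montage (Biosemi 32 layout) and the spatial weights used
# by the synthetic generator to place the pre-movement signature on the scalp.

#' Standard 32-channel 10-20 montage
#'
#' Electrode labels in recording order for the 32-channel layout used
#' throughout the package, together with the spatial weights the synthetic
#' generator applies when planting the pre-movement potential.
#'
#' @return A data frame with one row per electrode: `label` (10-20 name),
#'   `hemisphere` (-1 left, 0 midline, +1 right), `rp_weight` (weight of the
#'   non-lateralized slow ramp; largest over central/fronto-central sites,
#'   zero at posterior/neck-adjacent sites), and `lat_weight` (weight of the
#'   lateralized component; antisymmetric across the midline, zero on the
#'   midline and at posterior sites).
#' @export
#' @examples
#' m <- montage_32()
#' m[m$label %in% c("C3", "Cz", "C4"), ]
montage_32 <- function() {
  labels <- c("Fp1", "AF3", "F7", "F3", "FC1", "FC5", "T7", "C3",
              "CP1", "CP5", "P7", "P3", "Pz", "PO3", "O1", "Oz",
              "O2", "PO4", "P4", "P8", "CP6", "CP2", "C4", "T8",
              "FC6", "FC2", "F4", "F8", "AF4", "Fp2", "Fz", "Cz")
  # left-hemisphere weights; right counterparts are mirrored below
  rp <- c(Fp1 = 0.4, AF3 = 0.4, F7 = 0.3, F3 = 0.7, FC1 = 0.9, FC5 = 0.6,
          T7 = 0.2, C3 = 1.0, CP1 = 0.6, CP5 = 0.3, P7 = 0, P3 = 0.2,
          Pz = 0.2, PO3 = 0, O1 = 0, Oz = 0,
          Fz = 0.7, Cz = 1.0)
  lat <- c(Fp1 = 0.2, AF3 = 0.3, F7 = 0.3, F3 = 0.6, FC1 = 0.7, FC5 = 0.6,
           T7 = 0.2, C3 = 1.0, CP1 = 0.4, CP5 = 0.3, P7 = 0, P3 = 0,
           Pz = 0, PO3 = 0, O1 = 0, Oz = 0,
           Fz = 0, Cz = 0)
  mirror <- c(O2 = "O1", PO4 = "PO3", P4 = "P3", P8 = "P7", CP6 = "CP5",
              CP2 = "CP1", C4 = "C3", T8 = "T7", FC6 = "FC5", FC2 = "FC1",
              F4 = "F3", F8 = "F7", AF4 = "AF3", Fp2 = "Fp1")
  hemi <- ifelse(labels %in% c("Fz", "Cz", "Pz", "Oz"), 0L,
                 ifelse(labels %in% names(mirror), 1L, -1L))
  rp_w <- lat_w <- numeric(length(labels))
  for (i in seq_along(labels)) {
    lb <- labels[i]
    src <- if (lb %in% names(mirror)) mirror[[lb]] else lb
    rp_w[i] <- rp[[src]]
    # lateral weight carries the hemisphere sign: positive left, negative
    # right, zero midline, so the planted component is exactly antisymmetric
    lat_w[i] <- -hemi[i] * lat[[src]]
  }
  data.frame(label = labels, hemisphere = hemi,
             rp_weight = rp_w, lat_weight = lat_w,
             stringsAsFactors = FALSE)
}
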