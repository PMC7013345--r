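# Shared fixture builders.

# Disc of given value on a constant background.
discFrame <- function(dim = c(40, 40), center = c(20, 20), radius = 10,
                      value = 1000, background = 10, excitation = 405,
                      dose = 0) {
  rows <- matrix(seq_len(dim[1]), dim[1], dim[2])
  cols <- matrix(seq_len(dim[2]), dim[1], dim[2], byrow = TRUE)
  disc <- (rows - center[1])^2 + (cols - center[2])^2 <= radius^2
  px <- matrix(background, dim[1], dim[2])
  px[disc] <- value
  list(frame = fluorescenceFrame(px, excitation, dose), disc = disc)
}

# Pure absorber slab: transport has the Beer-Lambert closed form.
absorberModel <- function(mua = 1, thickness = 10)
  tissueModel(data.frame(name = "abs", thickness_mm = thickness, n = 1,
                         mua = mua, musp = 0))

tabulatedRates <- c(b405 = 0.011, b660 = 0.009, r405 = 0.014, r660 = 0.017)
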