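# Frozen reference-scale architecture tables (one row per reportable
# layer), shared by the network unit tests and the acceptance suite.

ref_generator_audit <- data.frame(
  layer = c("Dense", "Up sampling", "Conv3-128", "Up sampling", "Conv3-64",
            "Up sampling", "Conv3-32", "Up sampling", "Conv3-3"),
  h = c(8, 16, 16, 32, 32, 64, 64, 128, 128),
  w = c(8, 16, 16, 32, 32, 64, 64, 128, 128),
  c = c(128, 128, 128, 128, 64, 64, 32, 32, 3))

ref_discriminator_audit <- data.frame(
  layer = c("Conv3-16(stride size = 2)", "Conv3-32(stride size = 2)",
            "Zero padding", "Conv3-64(stride size = 2)", "Conv3-128",
            "Dense 1", "Dense 38"),
  h = c(64, 32, 33, 17, 17, NA, NA),
  w = c(64, 32, 33, 17, 17, NA, NA),
  c = c(16, 32, 32, 64, 128, 1, 38))

ref_classifier_audit <- data.frame(
  layer = c("Input Layer", "Conv3-64", "Conv3-64", "MaxPooling",
            "Conv3-128", "Conv3-128", "MaxPooling",
            "Conv3-256", "Conv3-256", "Conv3-256", "MaxPooling",
            "Conv3-512", "Conv3-512", "Conv3-512", "MaxPooling",
            "Conv3-512", "Conv3-512", "Conv3-512", "MaxPooling",
            "AverPooling", "Dense 512", "Dense 38"),
  h = c(128, 128, 128, 64, 64, 64, 32, 32, 32, 32, 16, 16, 16, 16, 8,
        8, 8, 8, 4, 1, NA, NA),
  w = c(128, 128, 128, 64, 64, 64, 32, 32, 32, 32, 16, 16, 16, 16, 8,
        8, 8, 8, 4, 1, NA, NA),
  c = c(3, 64, 64, 64, 128, 128, 128, 256, 256, 256, 256, 512, 512, 512,
        512, 512, 512, 512, 512, 512, 512, 38))

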