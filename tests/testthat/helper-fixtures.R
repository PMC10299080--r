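# Shared fixtures, built in code at test time.

# default ISI model, built once per test run
default_model <- isi_model()

# strictly periodic stimulus train
periodic_train <- function(period, duration, modality = "focal") {
  stimulus_train(seq(period, duration - 1e-9, by = period), modality, duration)
}

# raster from a plain 0/1 matrix (columns = electrodes 0, 1, ...)
raster_from <- function(mat, n_electrodes = ncol(mat)) {
  if (ncol(mat) < n_electrodes) {
    mat <- cbind(mat, matrix(0L, nrow(mat), n_electrodes - ncol(mat)))
  }
  binary_raster(mat)
}

stim_vec <- function(bins) {
  structure(list(bins = as.integer(bins), bin_width = 0.1),
            class = "stimulus_vector")
}

# 1-h focal-like session with perfectly reliable immediate responses
responsive_recording <- function(seed = 3, reliability = 1,
                                 response_latency = 0,
                                 response_duration = 0.2,
                                 duration = 3600, isi_seed = 2) {
  isis <- generate_isis(default_model, ceiling(duration / 4) + 20, seed = isi_seed)
  train <- isis_to_train(isis, duration, "focal")
  params <- network_params(reliability = reliability,
                           response_latency = response_latency,
                           response_duration = response_duration,
                           hourly_reliability_decay = 0, seed = seed)
  list(rec = simulate_recording(params, train, duration), train = train,
       params = params)
}

# plug-in MI by exhaustive double summation over an empirical joint table
mi_brute_force <- function(a, b) {
  ja <- table(a) / length(a)
  jb <- table(b) / length(b)
  jj <- table(a, b) / length(a)
  mi <- 0
  for (x in rownames(jj)) {
    for (y in colnames(jj)) {
      p <- jj[x, y]
      if (p > 0) mi <- mi + p * log2(p / (ja[[x]] * jb[[y]]))
    }
  }
  unname(mi)
}
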