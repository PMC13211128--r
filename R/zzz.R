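.onLoad <- function(libname, pkgname) {
  # feature maps churn through MB-sized allocations on every layer call;
  # keep them on the heap instead of per-allocation mmap round-trips
  cpp_tune_allocator()
  invisible()
}
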