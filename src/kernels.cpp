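#include <Rcpp.h>
#include <complex>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Gate kind codes shared with R (see compile_circuit()):
//   0 = H, 1 = X-type (X/CX/CCX/MCX), 2 = Z-type (Z/MCZ).
// Qubit j maps to bit position (width - 1 - j) of the basis-state index,
// i.e. qubit 0 is the leftmost character of a bitstring.

static inline long long qubit_mask(int width, int q) {
  return 1LL << (width - 1 - q);
}

// [[Rcpp::export]]
ComplexVector cpp_run_statevector(ComplexVector psi_in, int width,
                                  IntegerVector kind, List controls,
                                  IntegerVector target) {
  R_xlen_t dim = psi_in.size();
  std::vector< std::complex<double> > psi(dim);
  for (R_xlen_t i = 0; i < dim; ++i)
    psi[i] = std::complex<double>(psi_in[i].r, psi_in[i].i);

  const double inv_sqrt2 = 1.0 / std::sqrt(2.0);
  int ng = kind.size();
  for (int g = 0; g < ng; ++g) {
    long long tbit = qubit_mask(width, target[g]);
    IntegerVector ctl = controls[g];
    long long cmask = 0;
    for (int c = 0; c < ctl.size(); ++c) cmask |= qubit_mask(width, ctl[c]);

    if (kind[g] == 0) {            // Hadamard
      for (long long i = 0; i < dim; ++i) {
        if (i & tbit) continue;
        std::complex<double> a = psi[i], b = psi[i | tbit];
        psi[i]        = (a + b) * inv_sqrt2;
        psi[i | tbit] = (a - b) * inv_sqrt2;
      }
    } else if (kind[g] == 1) {     // X / CX / CCX / MCX
      for (long long i = 0; i < dim; ++i) {
        if (i & tbit) continue;
        if ((i & cmask) != cmask) continue;
        std::swap(psi[i], psi[i | tbit]);
      }
    } else {                       // Z / MCZ
      long long zmask = cmask | tbit;
      for (long long i = 0; i < dim; ++i)
        if ((i & zmask) == zmask) psi[i] = -psi[i];
    }
  }

  ComplexVector out(dim);
  for (R_xlen_t i = 0; i < dim; ++i) {
    out[i].r = psi[i].real();
    out[i].i = psi[i].imag();
  }
  return out;
}

// Classical reversible propagation of basis states with phase tracking.
// inputs: one basis state per row (0/1 integers, one column per qubit).
// Returns list(bits = matrix, phase = integer vector of +/-1).
// [[Rcpp::export]]
List cpp_evaluate_basis_batch(IntegerMatrix inputs, IntegerVector kind,
                              List controls, IntegerVector target) {
  int ng = kind.size();
  std::vector< std::vector<int> > ctl(ng);
  for (int g = 0; g < ng; ++g) {
    IntegerVector cv = controls[g];
    ctl[g].assign(cv.begin(), cv.end());
    if (kind[g] == 0) stop("basis-state evaluation cannot propagate H gates");
  }

  int nstates = inputs.nrow(), width = inputs.ncol();
  IntegerMatrix out_bits(nstates, width);
  IntegerVector phase(nstates);
  std::vector<int> bits(width);

  for (int s = 0; s < nstates; ++s) {
    for (int q = 0; q < width; ++q) bits[q] = inputs(s, q);
    int ph = 1;
    for (int g = 0; g < ng; ++g) {
      bool active = true;
      for (size_t c = 0; c < ctl[g].size(); ++c)
        if (!bits[ctl[g][c]]) { active = false; break; }
      if (!active) continue;
      if (kind[g] == 1) bits[target[g]] ^= 1;
      else if (bits[target[g]]) ph = -ph;   // Z-type
    }
    for (int q = 0; q < width; ++q) out_bits(s, q) = bits[q];
    phase[s] = ph;
  }
  return List::create(Named("bits") = out_bits, Named("phase") = phase);
}
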