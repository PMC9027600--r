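#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// 3D binary morphology and labelling on logical arrays stored in R's
// column-major order with dim = (n1, n2, n3).  Connectivity is 6-face
// throughout; the structuring element for dilate/erode is the discrete
// Euclidean ball of the given voxel radius.

static inline int idx3(int i, int j, int k, int n1, int n2) {
  return i + n1 * (j + n2 * k);
}

static std::vector<std::array<int, 3>> ball_offsets(int r) {
  std::vector<std::array<int, 3>> off;
  for (int dk = -r; dk <= r; ++dk)
    for (int dj = -r; dj <= r; ++dj)
      for (int di = -r; di <= r; ++di)
        if (di * di + dj * dj + dk * dk <= r * r)
          off.push_back({di, dj, dk});
  return off;
}

// [[Rcpp::export(name = ".cpp_binary_dilate")]]
LogicalVector cpp_binary_dilate(LogicalVector mask, IntegerVector dims, int radius) {
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  LogicalVector out(mask.size(), false);
  std::vector<std::array<int, 3>> off = ball_offsets(radius);
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        if (!mask[idx3(i, j, k, n1, n2)]) continue;
        for (auto &o : off) {
          int ii = i + o[0], jj = j + o[1], kk = k + o[2];
          if (ii >= 0 && ii < n1 && jj >= 0 && jj < n2 && kk >= 0 && kk < n3)
            out[idx3(ii, jj, kk, n1, n2)] = true;
        }
      }
  out.attr("dim") = dims;
  return out;
}

// [[Rcpp::export(name = ".cpp_binary_erode")]]
LogicalVector cpp_binary_erode(LogicalVector mask, IntegerVector dims, int radius) {
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  LogicalVector out(mask.size(), false);
  std::vector<std::array<int, 3>> off = ball_offsets(radius);
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        bool keep = mask[idx3(i, j, k, n1, n2)];
        if (keep) {
          for (auto &o : off) {
            int ii = i + o[0], jj = j + o[1], kk = k + o[2];
            // voxels outside the grid count as background
            if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 || kk < 0 || kk >= n3 ||
                !mask[idx3(ii, jj, kk, n1, n2)]) { keep = false; break; }
          }
        }
        out[idx3(i, j, k, n1, n2)] = keep;
      }
  out.attr("dim") = dims;
  return out;
}

// Label 6-connected foreground components; labels are 1..n_comp, 0 = background.
// [[Rcpp::export(name = ".cpp_label_components")]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims) {
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  IntegerVector lab(mask.size(), 0);
  int next = 0;
  const int d1[6] = {-1, 1, 0, 0, 0, 0};
  const int d2[6] = {0, 0, -1, 1, 0, 0};
  const int d3[6] = {0, 0, 0, 0, -1, 1};
  std::vector<int> stack;
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        int p = idx3(i, j, k, n1, n2);
        if (!mask[p] || lab[p]) continue;
        ++next;
        lab[p] = next;
        stack.clear();
        stack.push_back(p);
        while (!stack.empty()) {
          int q = stack.back();
          stack.pop_back();
          int qi = q % n1, qj = (q / n1) % n2, qk = q / (n1 * n2);
          for (int m = 0; m < 6; ++m) {
            int ii = qi + d1[m], jj = qj + d2[m], kk = qk + d3[m];
            if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 || kk < 0 || kk >= n3) continue;
            int r = idx3(ii, jj, kk, n1, n2);
            if (mask[r] && !lab[r]) { lab[r] = next; stack.push_back(r); }
          }
        }
      }
  lab.attr("dim") = dims;
  return lab;
}

// Fill holes independently within each axial slice (fixed axis-1 index):
// background 4-connected within the (row, col) plane that cannot be reached
// from the plane border is converted to foreground.
// [[Rcpp::export(name = ".cpp_fill_holes_slices")]]
LogicalVector cpp_fill_holes_slices(LogicalVector mask, IntegerVector dims) {
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  LogicalVector out = clone(mask);
  std::vector<char> reach(n2 * n3);
  std::vector<int> stack;
  for (int s = 0; s < n1; ++s) {
    std::fill(reach.begin(), reach.end(), 0);
    stack.clear();
    for (int j = 0; j < n2; ++j)
      for (int k = 0; k < n3; ++k) {
        if (j == 0 || j == n2 - 1 || k == 0 || k == n3 - 1) {
          if (!mask[idx3(s, j, k, n1, n2)] && !reach[j + n2 * k]) {
            reach[j + n2 * k] = 1;
            stack.push_back(j + n2 * k);
          }
        }
      }
    const int dj[4] = {-1, 1, 0, 0};
    const int dk[4] = {0, 0, -1, 1};
    while (!stack.empty()) {
      int q = stack.back();
      stack.pop_back();
      int qj = q % n2, qk = q / n2;
      for (int m = 0; m < 4; ++m) {
        int jj = qj + dj[m], kk = qk + dk[m];
        if (jj < 0 || jj >= n2 || kk < 0 || kk >= n3) continue;
        int r = jj + n2 * kk;
        if (!reach[r] && !mask[idx3(s, jj, kk, n1, n2)]) {
          reach[r] = 1;
          stack.push_back(r);
        }
      }
    }
    for (int j = 0; j < n2; ++j)
      for (int k = 0; k < n3; ++k)
        if (!mask[idx3(s, j, k, n1, n2)] && !reach[j + n2 * k])
          out[idx3(s, j, k, n1, n2)] = true;
  }
  out.attr("dim") = dims;
  return out;
}
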