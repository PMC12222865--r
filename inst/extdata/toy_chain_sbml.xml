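<?xml version="1.0" encoding="UTF-8"?>
<!-- Synthetic toy model: one carbon uptake feeding a biomass sink.
     Hand-written SBML Level 3 + fbc v2 used to exercise the reader on an
     externally formatted file (namespace prefixes, interleaved notes). -->
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"
      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"
      level="3" version="1" fbc:required="false">
  <model id="toy_chain_fixture" name="toy chain (synthetic)" fbc:strict="true">
    <listOfCompartments>
      <compartment id="e" name="extracellular" constant="true"/>
      <compartment id="c" name="cytosol" constant="true"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="M_glc_e" name="glucose" compartment="e"
               hasOnlySubstanceUnits="false" boundaryCondition="false"
               constant="false" fbc:chemicalFormula="C6H12O6"/>
      <species id="M_glc_c" name="glucose" compartment="c"
               hasOnlySubstanceUnits="false" boundaryCondition="false"
               constant="false" fbc:chemicalFormula="C6H12O6"/>
    </listOfSpecies>
    <listOfParameters>
      <parameter id="lb_uptake" value="-5" constant="true"/>
      <parameter id="lb_zero" value="0" constant="true"/>
      <parameter id="ub_default" value="1000" constant="true"/>
    </listOfParameters>
    <listOfReactions>
      <reaction id="R_EX_glc" reversible="true" fast="false"
                fbc:lowerFluxBound="lb_uptake" fbc:upperFluxBound="ub_default">
        <listOfReactants>
          <speciesReference species="M_glc_e" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
      <reaction id="R_TR_glc" reversible="false" fast="false"
                fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_default">
        <listOfReactants>
          <speciesReference species="M_glc_e" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="M_glc_c" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="R_biomass" reversible="false" fast="false"
                fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_default">
        <listOfReactants>
          <speciesReference species="M_glc_c" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
    </listOfReactions>
    <fbc:listOfObjectives fbc:activeObjective="obj">
      <fbc:objective fbc:id="obj" fbc:type="maximize">
        <fbc:listOfFluxObjectives>
          <fbc:fluxObjective fbc:reaction="R_biomass" fbc:coefficient="1"/>
        </fbc:listOfFluxObjectives>
      </fbc:objective>
    </fbc:listOfObjectives>
  </model>
</sbml>
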