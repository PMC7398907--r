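<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" level="3" version="1" fbc:required="false">
  <model id="TOY_1" fbc:strict="true">
    <listOfCompartments>
      <compartment id="c" name="cytosol" constant="true"/>
      <compartment id="e" name="extracellular" constant="true"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="glc_e" name="D-glucose" compartment="e" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false" fbc:chemicalFormula="C6H12O6" fbc:charge="0"/>
      <species id="glc_c" name="D-glucose" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false" fbc:chemicalFormula="C6H12O6" fbc:charge="0"/>
      <species id="nh4_e" name="ammonium" compartment="e" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false" fbc:chemicalFormula="H4N" fbc:charge="1"/>
      <species id="nh4_c" name="ammonium" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false" fbc:chemicalFormula="H4N" fbc:charge="1"/>
      <species id="biomass" name="biomass" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="true" constant="false"/>
    </listOfSpecies>
    <listOfParameters>
      <parameter id="fb_1" value="-1000" constant="true" sboTerm="SBO:0000626"/>
      <parameter id="fb_2" value="0" constant="true" sboTerm="SBO:0000626"/>
      <parameter id="fb_3" value="1000" constant="true" sboTerm="SBO:0000626"/>
    </listOfParameters>
    <listOfReactions>
      <reaction id="EX_glc" name="glucose exchange" reversible="false" fast="false" fbc:lowerFluxBound="fb_2" fbc:upperFluxBound="fb_3">
        <listOfReactants>
          <speciesReference species="glc_e" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
      <reaction id="EX_nh4" name="ammonium exchange" reversible="false" fast="false" fbc:lowerFluxBound="fb_2" fbc:upperFluxBound="fb_3">
        <listOfReactants>
          <speciesReference species="nh4_e" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
      <reaction id="T_glc" name="glucose transport" reversible="false" fast="false" fbc:lowerFluxBound="fb_2" fbc:upperFluxBound="fb_3">
        <listOfReactants>
          <speciesReference species="glc_e" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="glc_c" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="T_nh4" name="ammonium transport" reversible="true" fast="false" fbc:lowerFluxBound="fb_1" fbc:upperFluxBound="fb_3">
        <listOfReactants>
          <speciesReference species="nh4_e" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="nh4_c" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="BIOMASS" name="biomass" reversible="false" fast="false" fbc:lowerFluxBound="fb_2" fbc:upperFluxBound="fb_3">
        <listOfReactants>
          <speciesReference species="glc_c" stoichiometry="1" constant="true"/>
          <speciesReference species="nh4_c" stoichiometry="0.5" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="biomass" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
    </listOfReactions>
    <fbc:listOfObjectives fbc:activeObjective="obj">
      <fbc:objective fbc:id="obj" fbc:type="maximize">
        <fbc:listOfFluxObjectives>
          <fbc:fluxObjective fbc:reaction="BIOMASS" fbc:coefficient="1"/>
        </fbc:listOfFluxObjectives>
      </fbc:objective>
    </fbc:listOfObjectives>
  </model>
</sbml>
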